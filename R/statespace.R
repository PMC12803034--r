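#' Convert dwell mean levels from turns to base pairs unwound
#'
#' Rotor angles in turns convert to base pairs unwound via the B-DNA
#' helicity (`bp = turns * h`).
#'
#' @param dwells dwell table with `mean_level` in turns.
#' @param helicity bp per turn (default 10.5).
#' @return the dwell table with `mean_level` in bp and a `units` column.
#' @export
dwells_to_bp <- function(dwells, helicity = 10.5) {
  dwells$mean_level <- dwells$mean_level * helicity
  dwells$units <- "bp"
  dwells
}

dwell_lifetimes <- function(dwells) dwells$t_end_s - dwells$t_start_s

default_labels <- function(n) {
  if (n <= 4L) c("C", "I", "O", "Op")[seq_len(n)] else paste0("S", seq_len(n))
}

#' Cluster dwell levels into discrete R-loop states
#'
#' One-dimensional assignment of dwell mean levels (bp) to a fixed number
#' of states. Centers are lifetime-weighted mean unwinding values; state
#' boundaries are arithmetic means of adjacent centers; assignment and
#' center updates are iterated to a fixed point. Initial centers may be
#' supplied (the states of the assay are typically known a priori);
#' otherwise quantile-spread initialization over the dwell-mean range is
#' used.
#'
#' @param dwells dwell table with `mean_level` in bp and dwell times.
#' @param centers optional numeric vector of initial state centers (bp).
#' @param n_states number of states when `centers` is not given.
#' @param labels optional state labels (default C, I, O, ...).
#' @param max_iter iteration cap.
#' @return an object of class `state_model`: `labels`, `centers_bp`
#'   (strictly increasing), `boundaries_bp` (length `n_states - 1`).
#' @export
cluster_states <- function(dwells, centers = NULL, n_states = length(centers),
                           labels = NULL, max_iter = 100L) {
  mlev <- dwells$mean_level
  life <- dwell_lifetimes(dwells)
  if (is.null(centers)) {
    if (is.null(n_states) || n_states < 1L)
      stop("cluster_states: give centers or n_states")
    centers <- as.numeric(quantile(mlev, probs = (2 * seq_len(n_states) - 1) /
                                     (2 * n_states), names = FALSE))
  }
  n_states <- length(centers)
  if (length(unique(mlev)) < n_states)
    stop("cluster_states: fewer distinct dwell levels than requested states")
  if (is.null(labels)) labels <- default_labels(n_states)
  assign_prev <- NULL
  for (it in seq_len(max_iter)) {
    bounds <- (head(centers, -1L) + centers[-1L]) / 2
    idx <- findInterval(mlev, bounds, left.open = TRUE) + 1L
    if (identical(idx, assign_prev)) break
    assign_prev <- idx
    if (length(unique(idx)) < n_states)
      stop("cluster_states: a state lost all dwells during iteration; ",
           "fewer distinct dwell levels than requested states")
    centers <- as.numeric(tapply(seq_along(mlev), idx, function(ii)
      weighted.mean(mlev[ii], life[ii])))
    centers <- sort(centers)
  }
  structure(list(labels = labels, centers_bp = centers,
                 boundaries_bp = (head(centers, -1L) + centers[-1L]) / 2),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("State model:",
      paste(sprintf("%s at %.2f bp", x$labels, x$centers_bp), collapse = ", "),
      "\n")
  if (length(x$boundaries_bp))
    cat("  boundaries (bp):", paste(sprintf("%.2f", x$boundaries_bp),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Label, merge, and zero dwells against a state model
#'
#' Each dwell is labeled by the boundary interval containing its mean (a
#' mean exactly on a boundary goes to the lower state); consecutive
#' same-state dwells are merged (merged mean = lifetime-weighted mean of
#' the parts); all levels are then shifted so the lifetime-weighted mean of
#' the predominant closed state is 0 bp.
#'
#' The predominant closed state is the minimum-center state; if it is not
#' also the most-occupied state a warning is issued and zeroing still uses
#' the minimum-center state. Optionally, short-lived excursions beyond the
#' top state ("O-prime") are split off: dwells above the mirror point of
#' the top boundary about the top center get label `oprime_label`; they are
#' reported but typically excluded from C/I/O kinetics.
#'
#' @param dwells dwell table (bp) in time order.
#' @param model a `state_model` from [cluster_states()].
#' @param zero shift levels so the closed state sits at 0 bp (default TRUE).
#' @param oprime detect extended-opening excursions beyond the top state.
#' @param oprime_label label for those excursions (default "Op").
#' @return list with `dwells` (merged, labeled, zeroed; column `state`),
#'   `offset_bp` (the subtracted zero offset), and `model` (centers shifted
#'   by the same offset).
#' @export
assign_merge_zero <- function(dwells, model, zero = TRUE, oprime = FALSE,
                              oprime_label = "Op") {
  if (is.null(model$boundaries_bp) && length(model$labels) > 1L)
    stop("assign_merge_zero: model boundaries undefined")
  mlev <- dwells$mean_level
  idx <- findInterval(mlev, model$boundaries_bp, left.open = TRUE) + 1L
  lab <- model$labels[idx]
  if (oprime && length(model$centers_bp) > 1L) {
    nb <- length(model$boundaries_bp)
    cut <- 2 * model$centers_bp[nb + 1L] - model$boundaries_bp[nb]
    lab[mlev > cut] <- oprime_label
  }
  life <- dwell_lifetimes(dwells)
  runs <- rle(lab)
  grp <- rep(seq_along(runs$lengths), runs$lengths)
  merged <- data.frame(
    t_start_s = as.numeric(tapply(dwells$t_start_s, grp, min)),
    t_end_s = as.numeric(tapply(dwells$t_end_s, grp, max)),
    mean_level = as.numeric(tapply(seq_along(mlev), grp, function(ii)
      weighted.mean(mlev[ii], life[ii]))),
    n_samples = if ("n_samples" %in% names(dwells))
      as.numeric(tapply(dwells$n_samples, grp, sum)) else NA_real_,
    state = runs$values,
    stringsAsFactors = FALSE)
  merged <- merged[order(merged$t_start_s), , drop = FALSE]
  rownames(merged) <- NULL

  offset <- 0
  if (zero) {
    closed <- model$labels[1L]  # minimum-center state
    occ <- tapply(dwell_lifetimes(merged), merged$state, sum)
    core <- occ[names(occ) %in% model$labels]
    if (length(core) && names(core)[which.max(core)] != closed)
      warning("assign_merge_zero: minimum-center state '", closed,
              "' is not the most occupied; zeroing to it anyway")
    sel <- merged$state == closed
    if (!any(sel)) stop("assign_merge_zero: no dwells in the closed state")
    offset <- weighted.mean(merged$mean_level[sel],
                            dwell_lifetimes(merged)[sel])
    merged$mean_level <- merged$mean_level - offset
    model$centers_bp <- model$centers_bp - offset
    model$boundaries_bp <- model$boundaries_bp - offset
  }
  list(dwells = merged, offset_bp = offset, model = model)
}

#' Lifetime-weighted occupancy histogram
#'
#' Each dwell contributes its lifetime to the bin containing its mean
#' unwinding level; the histogram is normalized to total probability 1.
#'
#' @param dwells labeled (and typically zeroed) dwell table, bp.
#' @param bin_bp bin width in bp (default 0.5).
#' @return data frame with `bin_left_bp` and `probability` (sums to 1).
#' @export
occupancy_histogram <- function(dwells, bin_bp = 0.5) {
  life <- dwell_lifetimes(dwells)
  tot <- sum(life)
  if (tot <= 0) stop("occupancy_histogram: zero total lifetime")
  bin <- floor(dwells$mean_level / bin_bp) * bin_bp
  agg <- tapply(life, bin, sum)
  data.frame(bin_left_bp = as.numeric(names(agg)),
             probability = as.numeric(agg) / tot,
             row.names = NULL)
}
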