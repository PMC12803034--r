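#' Estimate OU noise parameters from a baseline segment
#'
#' Global noise parameters are fixed from a single-state portion of the
#' trace (for assay data, the span recorded before any RNP is introduced).
#' Uses the exact AR(1) discretization of the OU process: `sigma` is the
#' stationary standard deviation and `tau_c = -dt / log(r1)` from the lag-1
#' autocorrelation `r1` (the moment estimators coincide with
#' maximum likelihood to first order for long baselines).
#'
#' If the lag-1 autocorrelation is not positive the series is
#' white-noise-degenerate at this sampling rate; `tau_c` is then reported
#' as `dt / 100` (i.e. below `dt`) with a warning, and flagged.
#'
#' @param baseline numeric series (turns), assumed single-state.
#' @param dt sampling interval, s.
#' @param min_samples minimum baseline length (default 1000).
#' @return an [ou_params()] with attribute `"white_noise"` (logical).
#' @export
estimate_ou_params <- function(baseline, dt, min_samples = 1000L) {
  n <- length(baseline)
  if (n < min_samples)
    stop("estimate_ou_params: baseline has ", n, " samples; need >= ", min_samples)
  v <- var(baseline)
  if (!is.finite(v) || v <= 0)
    stop("estimate_ou_params: baseline variance is not positive")
  r1 <- cor(baseline[-1L], baseline[-n])
  white <- !is.finite(r1) || r1 <= 0
  if (white) {
    warning("estimate_ou_params: lag-1 autocorrelation <= 0; ",
            "correlation time unresolved at this dt (white-noise limit)")
    tau_c <- dt / 100
  } else {
    tau_c <- -dt / log(r1)
  }
  out <- ou_params(tau_c = tau_c, sigma = sqrt(v))
  attr(out, "white_noise") <- white
  out
}

# AR(1) whitening shared by segment_trace and oracle_segment.
# y[k] = x[k+1] - a x[k], k = 1..n-1; a segment of x starting at sample i
# (i >= 2) owns innovations y[i-1 .. j-1] (the cross-boundary innovation is
# assigned to the later segment); the first segment owns y[1 .. j-1] plus
# sample 1 itself.
whiten_ou <- function(x, dt, ou) {
  a <- exp(-dt / ou$tau_c)
  s2 <- ou$sigma^2 * (1 - a^2)
  list(y = x[-1L] - a * x[-length(x)], a = a, s2 = max(s2, .Machine$double.xmin))
}

# Build the dwell table from segment ends in y-index space.
# Reported dwell means are the conditional ML means computed from the
# segment's interior innovations (the boundary innovation, which reflects
# the level jump itself, is excluded), so noiseless steps yield exact means.
dwells_from_ends <- function(x, ends_y, w, dt) {
  n <- length(x)
  starts_y <- c(1L, head(ends_y, -1L) + 1L)
  start_x <- c(1L, starts_y[-1L] + 1L)
  end_x <- ends_y + 1L
  mean_lvl <- mapply(function(sy, ey, first) {
    yy <- w$y[if (first) sy:ey else (sy + 1L):ey]
    if (length(yy) == 0L) yy <- w$y[sy:ey]
    mean(yy) / (1 - w$a)
  }, starts_y, ends_y, c(TRUE, rep(FALSE, length(ends_y) - 1L)))
  data.frame(
    t_start_s = (start_x - 1L) * dt,
    t_end_s = end_x * dt,
    mean_level = as.numeric(mean_lvl),
    n_samples = end_x - start_x + 1L,
    state = NA_character_,
    stringsAsFactors = FALSE)
}

seg_objective <- function(y, ends_y, penalty_rss) {
  starts <- c(1L, head(ends_y, -1L) + 1L)
  rss <- sum(mapply(function(i, j) {
    yy <- y[i:j]; sum((yy - mean(yy))^2)
  }, starts, ends_y))
  rss + penalty_rss * (length(ends_y) - 1L)
}

new_segmentation <- function(x, dt, ou, penalty, ends_y, w) {
  dw <- dwells_from_ends(x, ends_y, w, dt)
  obj <- seg_objective(w$y, ends_y, 2 * w$s2 * penalty)
  rss <- obj - 2 * w$s2 * penalty * (length(ends_y) - 1L)
  ll <- -rss / (2 * w$s2) - length(w$y) / 2 * log(2 * pi * w$s2)
  structure(list(dwells = dw, ou = ou, penalty = penalty,
                 log_likelihood = ll, objective = obj,
                 changepoints = head(ends_y, -1L) + 2L),
            class = "rbt_segmentation")
}

#' @export
print.rbt_segmentation <- function(x, ...) {
  cat(sprintf("OU change-point segmentation: %d dwells (penalty %.3g, logL %.6g)\n",
              nrow(x$dwells), x$penalty, x$log_likelihood))
  invisible(x)
}

#' Segment a rotor-angle series under the OU observation model
#'
#' Detects change points in the mean level of a series whose fluctuations
#' follow a fixed Ornstein-Uhlenbeck noise model; only the per-segment mean
#' and the change-point times are free. The exact AR(1) transform turns the
#' OU likelihood into independent Gaussian innovations, so the penalized
#' maximum-likelihood segmentation reduces to a least-squares change-in-mean
#' problem on the whitened series, solved exactly by a pruned
#' optimal-partitioning dynamic program (PELT).
#'
#' The innovation that straddles a change point is assigned to the later
#' segment in the search cost; reported dwell means are conditional ML means
#' from each segment's interior innovations.
#'
#' @param x numeric series (turns or bp; units are the caller's).
#' @param dt sampling interval, s.
#' @param ou fixed [ou_params()] (not re-fit per segment).
#' @param penalty penalty per change point on the log-likelihood scale;
#'   default `2 * log(n)` (BIC-style: one mean plus one breakpoint).
#' @param min_dwell_samples minimum dwell length in samples (default 5).
#' @return an object of class `rbt_segmentation`: `dwells` data frame
#'   (`t_start_s`, `t_end_s`, `mean_level`, `n_samples`, `state`), the OU
#'   parameters, penalty, the full-series Gaussian `log_likelihood`, the
#'   penalized least-squares `objective`, and `changepoints` (sample
#'   indices of the first sample of each new dwell).
#' @export
segment_trace <- function(x, dt, ou, penalty = NULL, min_dwell_samples = 5L) {
  n <- length(x)
  if (n < 2L * min_dwell_samples)
    stop("segment_trace: series shorter than twice the minimum dwell length")
  if (is.null(penalty)) penalty <- 2 * log(n)
  w <- whiten_ou(x, dt, ou)
  ends <- pelt_mean_cpp(w$y, 2 * w$s2 * penalty, as.integer(min_dwell_samples))
  new_segmentation(x, dt, ou, penalty, as.integer(ends), w)
}

#' Exhaustive-search segmentation oracle
#'
#' Finds the global optimum of the same penalized OU likelihood as
#' [segment_trace()] by a segment-count-constrained dynamic program over
#' all admissible change-point placements (equivalent to exhaustive
#' enumeration, implemented independently of the PELT path). Intended for
#' validating [segment_trace()] on small instances.
#'
#' @param x numeric series, at most 2000 samples.
#' @param dt sampling interval, s.
#' @param ou fixed [ou_params()].
#' @param max_changes maximum number of change points (<= 3).
#' @param penalty penalty per change point (default `2 * log(n)`).
#' @param min_dwell_samples minimum dwell length (default 5).
#' @return an `rbt_segmentation` (same structure as [segment_trace()]).
#' @export
oracle_segment <- function(x, dt, ou, max_changes = 3L, penalty = NULL,
                           min_dwell_samples = 5L) {
  n <- length(x)
  if (n > 2000L) stop("oracle_segment: instance too large (> 2000 samples)")
  if (max_changes > 3L) stop("oracle_segment: max_changes must be <= 3")
  if (n < 2L * min_dwell_samples)
    stop("oracle_segment: series shorter than twice the minimum dwell length")
  if (is.null(penalty)) penalty <- 2 * log(n)
  w <- whiten_ou(x, dt, ou)
  y <- w$y
  m <- length(y)
  S <- c(0, cumsum(y)); S2 <- c(0, cumsum(y^2))
  rss <- function(i, j)  # vectorized over i
    (S2[j + 1L] - S2[i]) - (S[j + 1L] - S[i])^2 / (j - i + 1L)
  msl <- as.integer(min_dwell_samples)

  # F[[k+1]][j]: min RSS of y[1..j] split into k+1 segments; bk: last start
  K <- as.integer(max_changes)
  F <- matrix(Inf, nrow = K + 1L, ncol = m)
  B <- matrix(NA_integer_, nrow = K + 1L, ncol = m)
  js <- seq_len(m)
  F[1L, ] <- ifelse(js >= msl, rss(rep(1L, m), js), Inf)
  if (K >= 1L) for (k in seq_len(K)) {
    for (j in js) {
      if (j < (k + 1L) * msl) next
      i_last <- seq(k * msl + 1L, j - msl + 1L)  # start of the last segment
      v <- F[k, i_last - 1L] + rss(i_last, rep(j, length(i_last)))
      b <- which.min(v)
      F[k + 1L, j] <- v[b]
      B[k + 1L, j] <- i_last[b]
    }
  }
  lambda <- 2 * w$s2 * penalty
  tot <- F[, m] + lambda * (seq_len(K + 1L) - 1L)
  kbest <- which.min(tot)
  ends <- m
  j <- m; k <- kbest
  while (k > 1L) {
    i <- B[k, j]
    ends <- c(i - 1L, ends)
    j <- i - 1L; k <- k - 1L
  }
  new_segmentation(x, dt, ou, penalty, as.integer(ends), w)
}
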