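#' Transition rates from labeled dwells at fixed twist
#'
#' Counts transitions i -> j between consecutive merged dwells and divides
#' by the total time spent in state i. Counting starts after the first
#' transition event: the first dwell (and all time before the first
#' transition) is excluded from both counts and occupancy; the final
#' right-censored dwell contributes occupancy but no exit. Standard errors
#' assume Poisson statistics of transition events: `se = sqrt(N) / T_i`.
#'
#' @param dwells merged labeled dwell table in time order (columns
#'   `t_start_s`, `t_end_s`, `state`).
#' @param exclude state labels to drop before counting (default `"Op"`:
#'   extended-opening excursions are excluded from C/I/O kinetics).
#' @param drop_first exclude the first dwell and its entry transition
#'   (default TRUE, matching the equilibrium counting rule).
#' @return data frame of class `rate_table`: `from`, `to`, `n`,
#'   `occupancy_s`, `rate_s` (1/s), `se_s`. Ordered pairs with zero
#'   occupancy are omitted; pairs with occupancy but no events are kept
#'   with rate 0 and se 0.
#' @export
transition_rates <- function(dwells, exclude = "Op", drop_first = TRUE) {
  dw <- dwells[!(dwells$state %in% exclude), , drop = FALSE]
  if (nrow(dw) < 2L) {
    warning("transition_rates: fewer than two dwells; no transitions")
    return(empty_rate_table())
  }
  if (drop_first) dw <- dw[-1L, , drop = FALSE]
  if (nrow(dw) < 2L) {
    warning("transition_rates: no transitions after the first event")
    return(empty_rate_table())
  }
  states <- sort(unique(dw$state))
  occ <- tapply(dw$t_end_s - dw$t_start_s, dw$state, sum)
  from <- dw$state[-nrow(dw)]
  to <- dw$state[-1L]
  out <- expand.grid(from = states, to = states, stringsAsFactors = FALSE)
  out <- out[out$from != out$to, , drop = FALSE]
  out$n <- mapply(function(f, t) sum(from == f & to == t), out$from, out$to)
  out$occupancy_s <- as.numeric(occ[out$from])
  out <- out[out$occupancy_s > 0, , drop = FALSE]
  out$rate_s <- out$n / out$occupancy_s
  out$se_s <- sqrt(out$n) / out$occupancy_s
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

empty_rate_table <- function() {
  structure(data.frame(from = character(0), to = character(0),
                       n = integer(0), occupancy_s = numeric(0),
                       rate_s = numeric(0), se_s = numeric(0)),
            class = c("rate_table", "data.frame"))
}

#' Equilibrium constants, free energies, and barrier heights from rates
#'
#' For every pair with both directed rates measured and positive:
#' `K_ij = k_ij / k_ji`, `dG_ij = -ln K_ij` (kBT), and display-level
#' barrier heights `dG+_ij = -ln k_ij` with rates in 1/s against an
#' implicit unit attempt frequency. The standard error of `ln K` is
#' propagated from the Poisson counts as `sqrt(1/N_ij + 1/N_ji)`.
#' One-directional pairs are omitted (K undefined, not infinite).
#'
#' @param rates a `rate_table` from [transition_rates()].
#' @param order optional state order; pairs are reported with `from`
#'   earlier in this order. Default: alphabetical order of labels unless
#'   the labels are exactly C/I/O(/Op), which use that canonical order.
#' @return data frame of class `thermo_table`: `from`, `to`, `K`,
#'   `dG_kBT`, `se_lnK`, `barrier_fwd_kBT`, `barrier_rev_kBT`,
#'   `n_fwd`, `n_rev`.
#' @export
derive_thermodynamics <- function(rates, order = NULL) {
  labs <- unique(c(rates$from, rates$to))
  if (is.null(order)) {
    canon <- c("C", "I", "O", "Op")
    order <- if (all(labs %in% canon)) canon[canon %in% labs] else sort(labs)
  }
  rows <- list()
  if (length(order) >= 2L) for (a in seq_len(length(order) - 1L)) {
    for (b in seq((a + 1L), length(order))) {
      i <- order[a]; j <- order[b]
      fwd <- rates[rates$from == i & rates$to == j, , drop = FALSE]
      rev <- rates[rates$from == j & rates$to == i, , drop = FALSE]
      if (nrow(fwd) != 1L || nrow(rev) != 1L) next
      if (fwd$rate_s <= 0 || rev$rate_s <= 0) next
      K <- fwd$rate_s / rev$rate_s
      rows[[length(rows) + 1L]] <- data.frame(
        from = i, to = j, K = K, dG_kBT = -log(K),
        se_lnK = sqrt(1 / fwd$n + 1 / rev$n),
        barrier_fwd_kBT = -log(fwd$rate_s),
        barrier_rev_kBT = -log(rev$rate_s),
        n_fwd = fwd$n, n_rev = rev$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(0), to = character(0), K = numeric(0),
               dG_kBT = numeric(0), se_lnK = numeric(0),
               barrier_fwd_kBT = numeric(0), barrier_rev_kBT = numeric(0),
               n_fwd = integer(0), n_rev = integer(0))
  rownames(out) <- NULL
  class(out) <- c("thermo_table", "data.frame")
  out
}

#' Equilibrium free-energy landscape along the state order
#'
#' Well x-positions are the lifetime-weighted state centers (bp); well
#' energies are cumulative sums of the adjacent-pair free-energy
#' differences along the state order, with the closed reference state at
#' 0 kBT. Barrier energies sit at `well_i + dG+_{i->j}`; barrier
#' x-positions are midway between wells at this (zero-twist) stage. Direct
#' non-adjacent transitions are not part of the landscape path. A missing
#' adjacent pair truncates the landscape at the gap (flagged).
#'
#' @param thermo a `thermo_table` from [derive_thermodynamics()].
#' @param model a `state_model` (supplies order and centers).
#' @return list of class `rbt_landscape`: `wells` (label, `x_bp`,
#'   `energy_kBT`), `barriers` (pair, `x_bp`, `energy_kBT`), `truncated`.
#' @export
equilibrium_landscape <- function(thermo, model) {
  labs <- model$labels
  wells <- data.frame(label = labs[1L], x_bp = model$centers_bp[1L],
                      energy_kBT = 0, stringsAsFactors = FALSE)
  barriers <- NULL
  truncated <- FALSE
  e <- 0
  for (a in seq_len(length(labs) - 1L)) {
    i <- labs[a]; j <- labs[a + 1L]
    row <- thermo[thermo$from == i & thermo$to == j, , drop = FALSE]
    if (nrow(row) != 1L) {
      warning("equilibrium_landscape: missing adjacent pair ", i, "<->", j,
              "; landscape truncated")
      truncated <- TRUE
      break
    }
    barriers <- rbind(barriers, data.frame(
      pair = paste0(i, "-", j),
      x_bp = (model$centers_bp[a] + model$centers_bp[a + 1L]) / 2,
      energy_kBT = e + row$barrier_fwd_kBT, stringsAsFactors = FALSE))
    e <- e + row$dG_kBT
    wells <- rbind(wells, data.frame(label = j,
                                     x_bp = model$centers_bp[a + 1L],
                                     energy_kBT = e, stringsAsFactors = FALSE))
  }
  structure(list(wells = wells, barriers = barriers, truncated = truncated),
            class = "rbt_landscape")
}

#' @export
print.rbt_landscape <- function(x, ...) {
  cat("Free-energy landscape (kBT, reference = first well):\n")
  print(x$wells, row.names = FALSE)
  if (!is.null(x$barriers)) {
    cat("barriers:\n")
    print(x$barriers, row.names = FALSE)
  }
  if (isTRUE(x$truncated)) cat("  [truncated at a missing pair]\n")
  invisible(x)
}
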