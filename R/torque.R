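#' Torque from magnet and rotor angles
#'
#' In torque-driven mode the tether torque is read out through the angular
#' deflection across the calibrated transducer segment:
#' `tau = kappa_t_turn * (theta - psi)` with `kappa_t_turn = 2 pi
#' kappa_t_rad` (angles in turns). The magnet angle is zero-referenced by
#' subtracting the supplied offset (the zero-torque magnet position is a
#' hardware calibration and must be provided).
#'
#' @param trace a ramp-mode `rbt_trace` with `magnet_turns`.
#' @param zero_offset_turns magnet-angle zero offset, turns.
#' @return data frame of class `torque_series`: `time_s`, `theta_turns`
#'   (zero-referenced imposed twist), `torque_pNnm`.
#' @export
compute_torque <- function(trace, zero_offset_turns = 0) {
  if (!identical(trace$mode, "ramp") || is.null(trace$magnet_turns))
    stop("compute_torque: ramp-mode trace with magnet angles required")
  if (is.null(trace$tether$kappa_t_rad))
    stop("compute_torque: transducer stiffness missing from tether metadata")
  theta <- trace$magnet_turns - zero_offset_turns
  tau <- kappa_t_turn(trace$tether) * (theta - trace$rotor_turns)
  structure(data.frame(time_s = trace$time_s, theta_turns = theta,
                       torque_pNnm = tau),
            class = c("torque_series", "data.frame"))
}

#' Full-tether torsional stiffness from the torque-twist slope
#'
#' Least-squares slope of torque versus imposed twist over closed-state
#' spans (unperturbed B-DNA), converted from per-turn to per-radian. The
#' intercept is retained as a residual zero check.
#'
#' @param torque torque values, pN nm.
#' @param theta imposed twist, turns (same length).
#' @return list: `kappa_rad` (pN nm/rad), `kappa_turn` (pN nm/turn),
#'   `intercept_pNnm`, `n`.
#' @export
fit_tether_stiffness <- function(torque, theta) {
  if (length(torque) != length(theta))
    stop("fit_tether_stiffness: torque and theta lengths differ")
  if (length(torque) < 10L)
    stop("fit_tether_stiffness: fewer than 10 samples")
  if (var(theta) == 0)
    stop("fit_tether_stiffness: zero twist variance; slope not identifiable")
  fit <- lm(torque ~ theta)
  slope <- unname(coef(fit)[2L])
  list(kappa_rad = slope / (2 * pi), kappa_turn = slope,
       intercept_pNnm = unname(coef(fit)[1L]), n = length(torque))
}

#' Convert torque to base pairs unwound
#'
#' `dtheta0(bp) = h * (tau - tau_B) / (2 pi kappa_rad)` where `tau_B =
#' kappa_turn * theta` is the expected torque of unperturbed B-DNA at the
#' imposed twist; positive values mean unwinding.
#'
#' @param torque torque series, pN nm.
#' @param theta imposed twist, turns (same length).
#' @param kappa_rad full-tether torsional stiffness, pN nm/rad.
#' @param helicity bp per turn (default 10.5).
#' @return numeric vector of base pairs unwound.
#' @export
torque_to_unwinding <- function(torque, theta, kappa_rad, helicity = 10.5) {
  if (kappa_rad <= 0) stop("torque_to_unwinding: kappa_rad must be > 0")
  tau_B <- 2 * pi * kappa_rad * theta
  helicity * (torque - tau_B) / (2 * pi * kappa_rad)
}

#' Twist density of an imposed twist
#'
#' Imposed twist in turns divided by the relaxed linking number
#' `Lk0 = N / h` of the tether, as a signed percentage.
#'
#' @param imposed_turns imposed twist, turns.
#' @param tether a [tether_spec()].
#' @return signed percentage (e.g. -1.05 for -5 turns on 5000 bp).
#' @export
twist_density <- function(imposed_turns, tether) {
  100 * imposed_turns / lk0(tether)
}

#' Bin dwell kinetics by imposed twist
#'
#' Occupancy is accrued sample-by-sample into the bin of the instantaneous
#' imposed twist; each transition is counted in the bin of the twist at the
#' transition time. Per-bin rates are `k_ij = N_ij / T_i` with Poisson
#' standard errors; any (bin, pair) with fewer than `min_transitions`
#' sampled transitions is excluded. The first dwell and its entry
#' transition are dropped, so a single bin spanning all twist reproduces
#' the fixed-twist estimator exactly.
#'
#' Bins are `bin_width_turns` wide, aligned so bin centers sit at
#' half-integer multiples of the width.
#'
#' @param dwells merged labeled dwell table in time order.
#' @param theta_fun function mapping time (s) to imposed twist (turns),
#'   e.g. `approxfun(torque_series$time_s, torque_series$theta_turns)`.
#' @param dt sampling interval used to accrue occupancy, s.
#' @param bin_width_turns twist bin width (default 0.5).
#' @param min_transitions exclusion threshold (default 3).
#' @param exclude state labels dropped before binning (default `"Op"`).
#' @return data frame of class `twist_bins`: `theta_center_turns`, `from`,
#'   `to`, `n`, `occupancy_s`, `rate_s`, `se_s`. The twist at each dwell's
#'   onset is attached as attribute `"onset_theta"`.
#' @export
bin_kinetics_by_twist <- function(dwells, theta_fun, dt,
                                  bin_width_turns = 0.5,
                                  min_transitions = 3L, exclude = "Op") {
  dw <- dwells[!(dwells$state %in% exclude), , drop = FALSE]
  if (nrow(dw) < 3L) stop("bin_kinetics_by_twist: too few dwells")
  onset_theta <- theta_fun(dw$t_start_s)
  dw1 <- dw[-1L, , drop = FALSE]  # counting starts after the first transition

  bin_of <- function(th) floor(th / bin_width_turns)
  center_of <- function(b) (b + 0.5) * bin_width_turns

  # occupancy: global sample grid, each sample attributed to the dwell
  # containing it (samples in excluded spans are dropped)
  ts <- seq(min(dw1$t_start_s), max(dw1$t_end_s) - dt / 2, by = dt)
  di <- findInterval(ts, dw1$t_start_s)
  inside <- di >= 1L & ts < dw1$t_end_s[pmax(di, 1L)]
  occ <- data.frame(state = dw1$state[di[inside]],
                    bin = bin_of(theta_fun(ts[inside])),
                    stringsAsFactors = FALSE)
  occ <- stats::aggregate(cbind(occ_s = rep(dt, nrow(occ))) ~ state + bin,
                          data = occ, FUN = sum)

  # transitions between consecutive retained dwells, binned at event time
  from <- dw1$state[-nrow(dw1)]
  to <- dw1$state[-1L]
  tev <- dw1$t_start_s[-1L]
  ev <- data.frame(from = from, to = to, bin = bin_of(theta_fun(tev)),
                   stringsAsFactors = FALSE)
  cnt <- stats::aggregate(cbind(n = rep(1L, nrow(ev))) ~ from + to + bin,
                          data = ev, FUN = sum)

  out <- merge(cnt, occ, by.x = c("from", "bin"), by.y = c("state", "bin"))
  out <- out[out$n >= min_transitions & out$occ_s > 0, , drop = FALSE]
  out <- data.frame(theta_center_turns = center_of(out$bin),
                    from = out$from, to = out$to, n = out$n,
                    occupancy_s = out$occ_s,
                    rate_s = out$n / out$occ_s,
                    se_s = sqrt(out$n) / out$occ_s,
                    stringsAsFactors = FALSE)
  out <- out[order(out$theta_center_turns, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "onset_theta") <- data.frame(t_start_s = dw$t_start_s,
                                         state = dw$state,
                                         theta_onset_turns = onset_theta)
  class(out) <- c("twist_bins", "data.frame")
  out
}

#' Fit the linear twist dependence of equilibrium constants and rates
#'
#' For each adjacent state pair, weighted least squares of `ln K_ij` versus
#' bin-center twist (weights from the propagated Poisson error
#' `sqrt(1/N_ij + 1/N_ji)`), following
#' `ln K_ij(theta) = beta kappa_turn dtheta_ij theta - beta dG_ij(0)`;
#' the slope yields the equilibrium twist change `dtheta_ij =
#' slope / (beta kappa_turn)` and the intercept the zero-twist free-energy
#' difference `dG_ij(0) = -intercept` (kBT). The forward rate fit
#' `ln k_ij(theta) = beta kappa_turn dtheta+_ij theta + ln k_ij(0)` is
#' restricted to an approximately linear region: either supplied bounds or
#' an automatic selection (largest contiguous run of bins, shrunk from the
#' ends while the weighted R-squared is below `r2_threshold`). The barrier
#' fraction `dtheta+_ij / dtheta_ij` is computed for display, locating the
#' transition state fractionally between the wells.
#'
#' @param bins a `twist_bins` table.
#' @param tether a [tether_spec()] (supplies `beta` and `kappa_turn`).
#' @param order optional state order (default canonical C/I/O).
#' @param linear_region optional `c(theta_min, theta_max)` for the ln k
#'   fits; default automatic.
#' @param r2_threshold weighted R-squared threshold for the automatic
#'   linear-region selection (default 0.8).
#' @return data frame of class `twist_fits`, one row per pair: slopes and
#'   intercepts of the ln K and forward/reverse ln k fits with standard
#'   errors, `delta_theta_turns`, `delta_theta_bp`, `dG0_kBT`,
#'   `barrier_fraction`, `theta_min`, `theta_max`, `n_bins`.
#' @export
fit_twist_dependence <- function(bins, tether, order = NULL,
                                 linear_region = NULL, r2_threshold = 0.8) {
  labs <- unique(c(bins$from, bins$to))
  if (is.null(order)) {
    canon <- c("C", "I", "O", "Op")
    order <- if (all(labs %in% canon)) canon[canon %in% labs] else sort(labs)
  }
  bk <- beta_kBT(tether) * kappa_turn(tether)
  rows <- list()
  for (a in seq_len(max(length(order) - 1L, 0L))) {
    i <- order[a]; j <- order[a + 1L]
    fwd <- bins[bins$from == i & bins$to == j, , drop = FALSE]
    rev <- bins[bins$from == j & bins$to == i, , drop = FALSE]
    both <- merge(fwd, rev, by = "theta_center_turns",
                  suffixes = c("_f", "_r"))
    if (nrow(both) < 3L) next
    lnK <- log(both$rate_s_f / both$rate_s_r)
    w <- 1 / (1 / both$n_f + 1 / both$n_r)
    fitK <- lm(lnK ~ both$theta_center_turns, weights = w)
    sK <- unname(coef(fitK)[2L]); iK <- unname(coef(fitK)[1L])
    seK <- sqrt(diag(suppressWarnings(vcov(fitK))))

    lr <- select_linear_region(fwd$theta_center_turns, log(fwd$rate_s),
                               fwd$n, linear_region, r2_threshold)
    fsel <- fwd[lr, , drop = FALSE]
    fitk <- lm(log(fsel$rate_s) ~ fsel$theta_center_turns, weights = fsel$n)
    sk <- unname(coef(fitk)[2L]); ik <- unname(coef(fitk)[1L])
    sek <- sqrt(diag(suppressWarnings(vcov(fitk))))

    lrr <- select_linear_region(rev$theta_center_turns, log(rev$rate_s),
                                rev$n, linear_region, r2_threshold)
    rsel <- rev[lrr, , drop = FALSE]
    fitr <- lm(log(rsel$rate_s) ~ rsel$theta_center_turns, weights = rsel$n)
    skr <- unname(coef(fitr)[2L])

    dth <- sK / bk
    rows[[length(rows) + 1L]] <- data.frame(
      from = i, to = j,
      slope_lnK = sK, se_slope_lnK = seK[2L],
      intercept_lnK = iK, se_intercept_lnK = seK[1L],
      delta_theta_turns = dth,
      delta_theta_bp = -dth * tether$helicity,
      dG0_kBT = -iK,
      slope_lnk_fwd = sk, se_slope_lnk_fwd = sek[2L],
      lnk0_fwd = ik, slope_lnk_rev = skr,
      barrier_fraction = if (sK != 0) sk / sK else NA_real_,
      theta_min = min(fsel$theta_center_turns),
      theta_max = max(fsel$theta_center_turns),
      n_bins = nrow(both), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("fit_twist_dependence: no pair has >= 3 retained bins")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("twist_fits", "data.frame")
  out
}

# Largest contiguous run of bins used for a ln k fit: manual bounds if
# given; otherwise shrink from the worse-fitting end while weighted
# R-squared stays below the threshold (the generative law is linear, so
# this usually keeps everything).
select_linear_region <- function(theta, lnk, w, bounds, r2_threshold) {
  if (!is.null(bounds)) {
    sel <- which(theta >= bounds[1L] & theta <= bounds[2L])
    if (length(sel) < 3L) stop("select_linear_region: fewer than 3 bins in bounds")
    return(sel)
  }
  ord <- order(theta)
  lo <- 1L; hi <- length(ord)
  wr2 <- function(sel) {
    if (length(sel) < 3L) return(1)
    f <- lm(lnk[sel] ~ theta[sel], weights = w[sel])
    rss <- sum(w[sel] * stats::residuals(f)^2)
    tss <- sum(w[sel] * (lnk[sel] - weighted.mean(lnk[sel], w[sel]))^2)
    if (tss <= 0 || rss <= 1e-12 * tss) return(1)
    1 - rss / tss
  }
  while (hi - lo + 1L > 3L && wr2(ord[lo:hi]) < r2_threshold) {
    f <- lm(lnk[ord[lo:hi]] ~ theta[ord[lo:hi]], weights = w[ord[lo:hi]])
    r <- abs(stats::residuals(f))
    if (r[1L] >= r[length(r)]) lo <- lo + 1L else hi <- hi - 1L
  }
  ord[lo:hi]
}

#' Twist-dependent free-energy landscape from linear fits
#'
#' Well energies at imposed twist `theta` follow from the fitted linear
#' twist dependence of each adjacent pair, `dG_ij(theta) = dG_ij(0) -
#' slope_lnK * theta` (kBT), cumulated along the state order with the
#' closed well at 0. Well x-positions use the lifetime-weighted state
#' centers (the fitted `dtheta_ij` do not reliably track the physical
#' unwinding levels); barrier x-positions sit at the fractional position
#' `dtheta+_ij / dtheta_ij` between wells, and barrier heights come from
#' the forward ln k fit evaluated at `theta`.
#'
#' @param fits a `twist_fits` table.
#' @param model a `state_model` (well positions).
#' @param theta imposed twist, turns (scalar).
#' @return an `rbt_landscape` (see [equilibrium_landscape()]).
#' @export
twist_landscape <- function(fits, model, theta = 0) {
  labs <- model$labels
  wells <- data.frame(label = labs[1L], x_bp = model$centers_bp[1L],
                      energy_kBT = 0, stringsAsFactors = FALSE)
  barriers <- NULL
  truncated <- FALSE
  e <- 0
  for (a in seq_len(length(labs) - 1L)) {
    i <- labs[a]; j <- labs[a + 1L]
    row <- fits[fits$from == i & fits$to == j, , drop = FALSE]
    if (nrow(row) != 1L) {
      warning("twist_landscape: missing fit for pair ", i, "<->", j,
              "; landscape truncated")
      truncated <- TRUE
      break
    }
    frac <- row$barrier_fraction
    frac <- if (is.finite(frac)) min(max(frac, 0), 1) else 0.5
    xw <- model$centers_bp[a] + frac * (model$centers_bp[a + 1L] -
                                          model$centers_bp[a])
    barrier_e <- e - (row$slope_lnk_fwd * theta + row$lnk0_fwd)
    barriers <- rbind(barriers, data.frame(
      pair = paste0(i, "-", j), x_bp = xw, energy_kBT = barrier_e,
      stringsAsFactors = FALSE))
    e <- e + (row$dG0_kBT - row$slope_lnK * theta)
    wells <- rbind(wells, data.frame(label = j,
                                     x_bp = model$centers_bp[a + 1L],
                                     energy_kBT = e, stringsAsFactors = FALSE))
  }
  structure(list(wells = wells, barriers = barriers, truncated = truncated,
                 theta_turns = theta),
            class = "rbt_landscape")
}
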