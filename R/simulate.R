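#' Triangular twist-ramp profile
#'
#' Imposed magnet twist as a function of time for torque-driven assays: a
#' triangular wave between `low_turns` and `high_turns` swept at
#' `rate_rpm` magnet revolutions per minute, starting at `low_turns` and
#' ascending.
#'
#' @param low_turns,high_turns ramp bounds, turns (`low < high`).
#' @param rate_rpm magnet rotation rate, revolutions per minute.
#' @return a function of time (s) returning twist in turns, with the ramp
#'   parameters attached as attribute `"ramp"`.
#' @export
ramp_profile <- function(low_turns = -5, high_turns = 7.5, rate_rpm = 3) {
  if (!(low_turns < high_turns)) stop("ramp_profile: need low_turns < high_turns")
  if (rate_rpm <= 0) stop("ramp_profile: rate_rpm must be > 0")
  span <- high_turns - low_turns
  v <- rate_rpm / 60  # turns per second
  f <- function(t) {
    u <- (v * t) %% (2 * span)
    low_turns + ifelse(u < span, u, 2 * span - u)
  }
  attr(f, "ramp") <- list(low_turns = low_turns, high_turns = high_turns,
                          rate_rpm = rate_rpm)
  f
}

#' Simulate a hidden R-loop state path
#'
#' Continuous-time Markov switching among the model's states with
#' twist-dependent rates `k_ij(theta(t))`. Time-inhomogeneous switching is
#' simulated exactly by thinning against the supremum of each exit rate
#' over the twist range visited (the rate law is monotone in theta, so the
#' supremum sits at a range endpoint).
#'
#' @param spec a [state_spec()].
#' @param duration trace duration, s.
#' @param theta_of_t imposed twist: a constant (turns) or a function of
#'   time, e.g. [ramp_profile()].
#' @param start_state label of the initial state (default first label).
#' @param seed integer RNG seed, recorded in the result.
#' @return an object of class `rbt_path`: list with `switch_times` (s,
#'   strictly increasing), `states` (labels of the `length(switch_times)+1`
#'   inter-switch intervals), `duration`, `spec`, `seed`.
#' @export
simulate_state_path <- function(spec, duration, theta_of_t = 0,
                                start_state = spec$labels[1L], seed = 1L) {
  if (duration <= 0) stop("simulate_state_path: duration must be > 0")
  set.seed(seed)
  const_theta <- !is.function(theta_of_t)
  if (const_theta) {
    th_range <- c(theta_of_t, theta_of_t)
    th_fun <- function(t) rep(theta_of_t, length(t))
  } else {
    tg <- seq(0, duration, length.out = 10001L)
    thv <- theta_of_t(tg)
    th_range <- range(thv)
    th_fun <- theta_of_t
  }
  tr <- spec$transitions
  if (is.null(tr)) {  # single state: one dwell spans the duration
    return(structure(list(switch_times = numeric(0), states = start_state,
                          duration = duration, spec = spec, seed = seed),
                     class = "rbt_path"))
  }
  bk <- beta_kBT(spec$tether) * kappa_turn(spec$tether)
  sup_rate <- pmax(tr$k0 * exp(bk * tr$dtheta_dagger_turns * th_range[1L]),
                   tr$k0 * exp(bk * tr$dtheta_dagger_turns * th_range[2L]))
  if (any(!is.finite(sup_rate))) {
    bad <- which(!is.finite(sup_rate))[1L]
    stop("simulate_state_path: non-finite rate for ", tr$from[bad], "->",
         tr$to[bad], " over the visited twist range")
  }
  stopifnot(start_state %in% spec$labels)
  idx_by_state <- split(seq_len(nrow(tr)), tr$from)

  t_now <- 0
  s_now <- start_state
  switch_times <- numeric(0)
  states <- s_now
  repeat {
    ii <- idx_by_state[[s_now]]
    lam <- sum(sup_rate[ii])
    if (is.null(ii) || lam <= 0) break
    t_now <- t_now + rexp(1L, lam)
    if (t_now >= duration) break
    th <- th_fun(t_now)
    k_now <- tr$k0[ii] * exp(bk * tr$dtheta_dagger_turns[ii] * th)
    if (runif(1L) < sum(k_now) / lam) {  # accept a real transition
      dest <- tr$to[ii][sample.int(length(ii), 1L, prob = k_now)]
      switch_times <- c(switch_times, t_now)
      states <- c(states, dest)
      s_now <- dest
    }
  }
  structure(list(switch_times = switch_times, states = states,
                 duration = duration, spec = spec, seed = seed),
            class = "rbt_path")
}

#' State occupied at given times
#'
#' @param path an `rbt_path`.
#' @param times numeric vector of times, s.
#' @return character vector of state labels.
#' @export
state_at <- function(path, times) {
  path$states[findInterval(times, path$switch_times) + 1L]
}

#' @export
print.rbt_path <- function(x, ...) {
  cat(sprintf("Hidden state path: %d switches over %.4g s (%d states)\n",
              length(x$switch_times), x$duration, length(x$spec$labels)))
  invisible(x)
}

# AR(1)-exact OU noise about a fixed mean (used in ramp mode, where the
# deterministic rotor mean is added separately):
# e_n = a e_{n-1} + sqrt(1-a^2) sigma xi_n, e_0 ~ N(0, sigma^2).
ou_noise <- function(n, dt, ou) {
  if (ou$sigma == 0) return(numeric(n))
  a <- exp(-dt / ou$tau_c)
  innov <- rnorm(n, 0, ou$sigma * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive",
                           init = rnorm(1L, 0, ou$sigma)))
}

# Exact-discretization OU relaxation toward a (possibly switching) mean:
# psi_n = mu_n + (psi_{n-1} - mu_n) a + sqrt(1-a^2) sigma xi_n.
# After a state switch the bead relaxes toward the new mean over tau_c,
# so the AR(1)-whitened series is exactly (1-a) mu_n plus white noise --
# the observation model the change-point segmentation assumes.
ou_relax <- function(mu, dt, ou) {
  a <- exp(-dt / ou$tau_c)
  s <- ou$sigma * sqrt(1 - a^2)
  innov <- if (ou$sigma == 0) numeric(length(mu)) else rnorm(length(mu), 0, s)
  init <- mu[1L] + if (ou$sigma == 0) 0 else rnorm(1L, 0, ou$sigma)
  as.numeric(stats::filter((1 - a) * mu + innov, a, method = "recursive",
                           init = init))
}

new_trace <- function(time_s, rotor_turns, magnet_turns, dt, mode, tether, seed) {
  structure(list(time_s = time_s, rotor_turns = rotor_turns,
                 magnet_turns = magnet_turns, dt = dt, mode = mode,
                 tether = tether, seed = seed),
            class = "rbt_trace")
}

#' @export
print.rbt_trace <- function(x, ...) {
  cat(sprintf("AuRBT trace (%s mode): %d samples at dt = %.3g s (%.4g s)\n",
              x$mode, length(x$rotor_turns), x$dt,
              length(x$rotor_turns) * x$dt))
  invisible(x)
}

#' Simulate a torsionally relaxed AuRBT trace
#'
#' Generates a hidden state path at zero twist and emits the rotor angle as
#' an exact-discretization OU process relaxing toward the state-dependent
#' mean `x_state / h` turns (rotor angle converts to base pairs unwound via
#' the B-DNA helicity). In the noiseless limit the trace equals the
#' piecewise-constant state means up to the geometric relaxation tail
#' (decay `exp(-dt/tau_c)` per sample) after each switch.
#'
#' @param spec a [state_spec()].
#' @param ou an [ou_params()].
#' @param duration trace duration, s.
#' @param dt sampling interval, s (default 1/5000: 5 kHz).
#' @param seed integer RNG seed.
#' @param start_state initial state label.
#' @return list with elements `trace` (`rbt_trace`) and `truth`
#'   (`rbt_path` plus the OU parameters as attribute `"ou"`).
#' @export
simulate_relaxed_trace <- function(spec, ou, duration, dt = 1 / 5000,
                                   seed = 1L, start_state = spec$labels[1L]) {
  if (duration <= 0 || dt <= 0)
    stop("simulate_relaxed_trace: duration and dt must be > 0")
  if (dt >= ou$tau_c)
    warning("simulate_relaxed_trace: dt >= tau_c; OU correlation is barely resolved")
  path <- simulate_state_path(spec, duration, theta_of_t = 0,
                              start_state = start_state, seed = seed)
  n <- floor(duration / dt)
  tt <- (seq_len(n) - 1L) * dt
  x_bp <- spec$unwinding_bp[match(state_at(path, tt), spec$labels)]
  mu <- x_bp / spec$tether$helicity
  psi <- ou_relax(mu, dt, ou)
  trace <- new_trace(tt, psi, NULL, dt, "relaxed", spec$tether, seed)
  attr(path, "ou") <- ou
  list(trace = trace, truth = path)
}

#' Simulate a torque-driven (twist ramp) AuRBT trace
#'
#' The magnet angle follows a triangular ramp; the hidden state path is
#' generated with twist-dependent rates. The instantaneous tether torque is
#' `tau(t) = kappa_turn (theta(t) + x(t)/h)` (unwinding absorbs `-x/h`
#' turns of duplex twist), the mean rotor angle is `theta(t) -
#' tau(t)/kappa_t_turn` (angular deflection across the transducer), and
#' stationary OU noise is added about that mean, so the torque read-out
#' inverts the generative model exactly in the noiseless limit.
#'
#' @param spec a [state_spec()].
#' @param ou an [ou_params()].
#' @param ramp a [ramp_profile()] or list with `low_turns`, `high_turns`,
#'   `rate_rpm`.
#' @param duration trace duration, s.
#' @param dt sampling interval, s.
#' @param seed integer RNG seed.
#' @param start_state initial state label.
#' @return list with `trace` (`rbt_trace`, with `magnet_turns`) and `truth`
#'   (`rbt_path` with OU attribute).
#' @export
simulate_ramp_trace <- function(spec, ou, ramp = ramp_profile(),
                                duration, dt = 1 / 5000, seed = 1L,
                                start_state = spec$labels[1L]) {
  if (duration <= 0 || dt <= 0)
    stop("simulate_ramp_trace: duration and dt must be > 0")
  if (!is.function(ramp))
    ramp <- ramp_profile(ramp$low_turns, ramp$high_turns, ramp$rate_rpm)
  path <- simulate_state_path(spec, duration, theta_of_t = ramp,
                              start_state = start_state, seed = seed)
  n <- floor(duration / dt)
  tt <- (seq_len(n) - 1L) * dt
  theta <- ramp(tt)
  x_bp <- spec$unwinding_bp[match(state_at(path, tt), spec$labels)]
  tau <- kappa_turn(spec$tether) * (theta + x_bp / spec$tether$helicity)
  psi_mean <- theta - tau / kappa_t_turn(spec$tether)
  psi <- psi_mean + ou_noise(n, dt, ou)
  trace <- new_trace(tt, psi, theta, dt, "ramp", spec$tether, seed)
  attr(path, "ou") <- ou
  list(trace = trace, truth = path)
}

#' Simulate a bulk cleavage time course
#'
#' Per-replicate cleaved fractions follow `A (1 - exp(-kobs t))` plus
#' Gaussian noise, clipped to `[0, 1]` (gel fractions are bounded).
#'
#' @param A amplitude in `(0, 1]`.
#' @param kobs_per_min apparent rate, 1/min (>= 0).
#' @param times_min sampling times, min (default: the 7-point quench grid
#'   0.5, 1, 5, 10, 30, 60, 120).
#' @param noise_sd Gaussian noise SD on fractions.
#' @param n_reps number of independent replicates.
#' @param seed integer RNG seed.
#' @return data frame with columns `time_min`, `replicate`, `fraction`,
#'   seed recorded as attribute `"seed"`.
#' @export
simulate_cleavage_timecourse <- function(A = 0.8, kobs_per_min = 0.2,
                                         times_min = c(0.5, 1, 5, 10, 30, 60, 120),
                                         noise_sd = 0.02, n_reps = 3L,
                                         seed = 1L) {
  if (A <= 0 || A > 1) stop("simulate_cleavage_timecourse: A must be in (0, 1]")
  if (kobs_per_min < 0) stop("simulate_cleavage_timecourse: kobs must be >= 0")
  if (length(times_min) == 0L) stop("simulate_cleavage_timecourse: empty times")
  if (any(times_min < 0)) stop("simulate_cleavage_timecourse: negative times")
  if (noise_sd < 0) stop("simulate_cleavage_timecourse: negative noise_sd")
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    y <- A * (1 - exp(-kobs_per_min * times_min)) +
      rnorm(length(times_min), 0, noise_sd)
    data.frame(time_min = times_min, replicate = r,
               fraction = pmin(pmax(y, 0), 1))
  }))
  attr(out, "seed") <- seed
  out
}

#' Decimate a trace for analysis
#'
#' Keeps every `factor`-th sample. Subsampling an exact-discretization OU
#' process yields the same OU process at the coarser interval (same `tau_c`
#' and `sigma`), so no noise-parameter adjustment is needed.
#'
#' @param trace an `rbt_trace`.
#' @param factor integer decimation factor >= 1.
#' @return the decimated `rbt_trace`.
#' @export
decimate_trace <- function(trace, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("decimate_trace: factor must be >= 1")
  if (factor == 1L) return(trace)
  keep <- seq(1L, length(trace$rotor_turns), by = factor)
  trace$time_s <- trace$time_s[keep]
  trace$rotor_turns <- trace$rotor_turns[keep]
  if (!is.null(trace$magnet_turns))
    trace$magnet_turns <- trace$magnet_turns[keep]
  trace$dt <- trace$dt * factor
  trace
}
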