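# Shared fixtures: canonical three-state model, default tether/noise, and a
# direct AR(1) OU generator independent of the package's trace simulator
# (used when a test needs noise without hidden-state switching).

fix_tether <- function(...) tether_spec(...)

fix_spec3 <- function(tether = fix_tether()) {
  state_spec(c("C", "I", "O"), c(0, 7, 14),
             k0 = c("C->I" = 0.2, "I->C" = 0.5, "I->O" = 0.1, "O->I" = 0.3),
             barrier_frac = 0.4, tether = tether)
}

# plain AR(1) recursion, scalar loop kept deliberately naive
ou_series <- function(n, dt, tau_c, sigma, mu = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- exp(-dt / tau_c)
  x <- numeric(n)
  x[1] <- mu + rnorm(1, 0, sigma)
  s <- sigma * sqrt(1 - a^2)
  for (i in 2:n) x[i] <- mu + a * (x[i - 1] - mu) + rnorm(1, 0, s)
  x
}

# piecewise-mean OU trace with known change points (x-sample indices of the
# first sample of each new level)
stepped_ou <- function(levels, seg_len, dt, tau_c, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- rep(levels, times = seg_len)
  n <- length(mu)
  a <- exp(-dt / tau_c)
  noise <- as.numeric(stats::filter(rnorm(n, 0, sigma * sqrt(1 - a^2)),
                                    a, method = "recursive",
                                    init = rnorm(1, 0, sigma)))
  mu + noise
}

# dwell table builder for hand-constructed sequences
dwell_df <- function(states, lifetimes, means = NULL) {
  ends <- cumsum(lifetimes)
  data.frame(t_start_s = c(0, head(ends, -1)), t_end_s = ends,
             mean_level = if (is.null(means)) rep(0, length(states)) else means,
             n_samples = NA_real_, state = states,
             stringsAsFactors = FALSE)
}
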