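test_that("spec constructors enforce their invariants", {
  expect_error(tether_spec(helicity = 9), "helicity")
  expect_error(tether_spec(kappa_rad = -1), "positive")
  expect_error(ou_params(tau_c = 0), "tau_c")
  expect_error(state_spec(c("C", "I"), c(7, 0),
                          k0 = c("C->I" = 1, "I->C" = 1)), "increasing")
  expect_error(state_spec(c("C", "I"), c(0, 7), k0 = c("C->I" = 1)),
               "I->C")
  expect_error(state_spec(c("C", "I"), c(0, 7),
                          k0 = c("C->I" = 1, "I->C" = 1),
                          barrier_frac = 1.2), "barrier")
  te <- fix_tether()
  expect_equal(lk0(te), 5000 / 10.5)
})

test_that("state_spec wires detailed-balance-consistent twist couplings", {
  sp <- fix_spec3()
  tr <- sp$transitions
  ci <- tr[tr$from == "C" & tr$to == "I", ]
  ic <- tr[tr$from == "I" & tr$to == "C", ]
  expect_equal(ci$dtheta_turns, -7 / 10.5)
  expect_equal(ci$dtheta_dagger_turns, 0.4 * (-7 / 10.5))
  # forward minus reverse barrier twist equals the equilibrium twist change
  expect_equal(ci$dtheta_dagger_turns - ic$dtheta_dagger_turns,
               ci$dtheta_turns)
  # reverse barrier twist lies between 0 and the reverse equilibrium change
  expect_gte(ic$dtheta_dagger_turns, 0)
  expect_lte(ic$dtheta_dagger_turns, ic$dtheta_turns)
})

test_that("analytic rate-ratio law holds exactly at any twist", {
  sp <- fix_spec3()
  bk <- (1 / 4.114) * 2 * pi * fix_tether()$kappa_rad
  for (th in c(-5, -1.3, 0, 2.2, 7.5)) {
    r <- transition_rates_at(sp, th)
    kf <- r$rate[r$from == "C" & r$to == "I"]
    kr <- r$rate[r$from == "I" & r$to == "C"]
    expect_equal(kf / kr, (0.2 / 0.5) * exp(bk * (-7 / 10.5) * th))
    expect_equal(equilibrium_ratio_at(sp, "C", "I", th), kf / kr)
  }
})

test_that("single state yields one dwell spanning the duration", {
  p <- simulate_state_path(state_spec("C", 0), duration = 12, seed = 3)
  expect_length(p$switch_times, 0)
  expect_identical(p$states, "C")
  expect_identical(state_at(p, c(0, 6, 11.9)), rep("C", 3))
})

test_that("two-state CTMC dwell means match 1/exit-rate within 5%", {
  sp <- state_spec(c("C", "I"), c(0, 7),
                   k0 = c("C->I" = 1, "I->C" = 1), tether = fix_tether())
  p <- simulate_state_path(sp, duration = 10000, theta_of_t = 0, seed = 101)
  bounds <- c(0, p$switch_times, p$duration)
  dur <- diff(bounds)
  st <- p$states
  # drop the censored final dwell
  for (lab in c("C", "I")) {
    d <- dur[-length(dur)][st[-length(st)] == lab]
    expect_gt(length(d), 1000)
    expect_lt(abs(mean(d) - 1), 0.05)
  }
})

test_that("three-state occupancies match the analytic stationary law", {
  # brute-force stationary distribution of the generator matrix
  sp <- fix_spec3()
  Q <- matrix(0, 3, 3, dimnames = list(sp$labels, sp$labels))
  for (i in seq_len(nrow(sp$transitions)))
    Q[sp$transitions$from[i], sp$transitions$to[i]] <- sp$transitions$k0[i]
  diag(Q) <- -rowSums(Q)
  # solve pi Q = 0 with sum(pi) = 1
  A <- rbind(t(Q), rep(1, 3))
  pi_st <- qr.solve(A, c(0, 0, 0, 1))
  p <- simulate_state_path(sp, duration = 20000, seed = 7)
  bounds <- c(0, p$switch_times, p$duration)
  occ <- tapply(diff(bounds), p$states, sum) / p$duration
  expect_equal(as.numeric(occ[sp$labels]), unname(pi_st), tolerance = 0.05)
  # I occupancy intermediate between C and O when I->C dominates
  expect_gt(occ[["C"]], occ[["I"]])
  expect_gt(occ[["I"]], occ[["O"]])
})

test_that("empirical transition counts agree with the generator (Poisson 3 sigma)", {
  sp <- fix_spec3()
  dur <- 20000
  p <- simulate_state_path(sp, duration = dur, seed = 21)
  bounds <- c(0, p$switch_times, dur)
  occ <- tapply(diff(bounds), p$states, sum)
  from <- p$states[-length(p$states)]
  to <- p$states[-1L]
  for (i in seq_len(nrow(sp$transitions))) {
    tr <- sp$transitions[i, ]
    n_obs <- sum(from == tr$from & to == tr$to)
    n_exp <- tr$k0 * occ[[tr$from]]
    expect_lt(abs(n_obs - n_exp), 3 * sqrt(n_exp))
  }
})

test_that("noiseless relaxed traces settle exactly onto the state means", {
  sp <- fix_spec3()
  ou <- ou_params(5e-3, 0)
  sim <- simulate_relaxed_trace(sp, ou, duration = 30, dt = 1e-3, seed = 5)
  tt <- sim$trace$time_s
  x_bp <- sp$unwinding_bp[match(state_at(sim$truth, tt), sp$labels)]
  # beyond the relaxation tail of each switch the trace is the state mean
  since_switch <- tt - c(0, sim$truth$switch_times)[
    findInterval(tt, sim$truth$switch_times) + 1L]
  settled <- since_switch > 30 * ou$tau_c
  expect_gt(mean(settled), 0.9)
  expect_equal(sim$trace$rotor_turns[settled], (x_bp / 10.5)[settled],
               tolerance = 1e-9)
  expect_null(sim$trace$magnet_turns)
  expect_identical(sim$trace$seed, 5)
})

test_that("OU noise has the stated stationary SD, autocorrelation time, and lag-1 identity", {
  ou <- ou_params(5e-3, 0.05)
  sim <- simulate_relaxed_trace(state_spec("C", 0), ou, duration = 100,
                                dt = 1 / 5000, seed = 9)
  x <- sim$trace$rotor_turns
  expect_lt(abs(sd(x) / ou$sigma - 1), 0.03)
  r1 <- cor(x[-1], x[-length(x)])
  tau_hat <- -sim$trace$dt / log(r1)
  expect_lt(abs(tau_hat / ou$tau_c - 1), 0.05)
})

test_that("identical seeds give bit-identical traces; different seeds differ", {
  sp <- fix_spec3()
  ou <- ou_params()
  a <- simulate_relaxed_trace(sp, ou, duration = 5, seed = 11)
  b <- simulate_relaxed_trace(sp, ou, duration = 5, seed = 11)
  c <- simulate_relaxed_trace(sp, ou, duration = 5, seed = 12)
  expect_identical(a$trace$rotor_turns, b$trace$rotor_turns)
  expect_identical(a$truth$switch_times, b$truth$switch_times)
  expect_false(identical(a$trace$rotor_turns, c$trace$rotor_turns))
})

test_that("ramp traces follow the triangular profile and the torque model", {
  rp <- ramp_profile(-5, 7.5, 3)
  expect_equal(rp(0), -5)
  expect_equal(rp(250), 7.5)           # 12.5 turns at 0.05 turns/s
  expect_equal(rp(500), -5)            # full period
  expect_error(ramp_profile(2, 2), "low")
  expect_error(ramp_profile(-5, 7.5, 0), "rate")

  # closed-only noiseless ramp: tau from the emitted trace is kappa_turn*theta
  te <- fix_tether()
  sim <- simulate_ramp_trace(state_spec("C", 0, tether = te),
                             ou_params(5e-3, 0), rp, duration = 100,
                             dt = 1e-3, seed = 2)
  tq <- compute_torque(sim$trace, 0)
  expect_equal(tq$torque_pNnm, 2 * pi * te$kappa_rad * tq$theta_turns,
               tolerance = 1e-12)
})

test_that("cleavage time courses honor the mono-exponential with clipping", {
  tc0 <- simulate_cleavage_timecourse(A = 0.8, kobs_per_min = 0,
                                      noise_sd = 0.01, seed = 4)
  expect_true(all(tc0$fraction >= 0 & tc0$fraction <= 1))
  expect_lt(max(tc0$fraction), 0.05)

  tcA <- simulate_cleavage_timecourse(A = 0.7, kobs_per_min = 50,
                                      times_min = c(100, 200), noise_sd = 0,
                                      n_reps = 2, seed = 4)
  expect_equal(tcA$fraction, rep(0.7, 4))

  expect_equal(sort(unique(simulate_cleavage_timecourse(seed = 1)$time_min)),
               c(0.5, 1, 5, 10, 30, 60, 120))
  expect_equal(max(simulate_cleavage_timecourse(seed = 1)$replicate), 3)
  expect_error(simulate_cleavage_timecourse(A = 0), "A must")
  expect_error(simulate_cleavage_timecourse(times_min = numeric(0)), "empty")
  expect_error(simulate_cleavage_timecourse(noise_sd = -1), "noise_sd")
})
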