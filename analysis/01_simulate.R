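#!/usr/bin/env Rscript
# Generate the synthetic data set used by the downstream analysis drivers:
# a torsionally relaxed AuRBT trace (three-state R-loop dynamics at zero
# twist), a torque-driven twist-ramp trace with its closed-duplex
# calibration ramp, and bulk cleavage time courses for a slow "wild-type"
# and a fast "optimized" variant. Large traces go to scratch/ (not a
# deliverable); small tables go to results/.

suppressPackageStartupMessages(library(aurbt))
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

seed <- 20260927L %% 100000L

tether <- tether_spec(length_bp = 5000, kappa_rad = 0.4)
ou <- ou_params(tau_c = 5e-3, sigma = 0.05)

## relaxed assay: C (0 bp) <-> I (~7 bp) <-> O (~14 bp)
spec3 <- state_spec(c("C", "I", "O"), c(0, 7, 14),
                    k0 = c("C->I" = 0.2, "I->C" = 0.5,
                           "I->O" = 0.1, "O->I" = 0.3),
                    barrier_frac = 0.4, tether = tether)
rel <- simulate_relaxed_trace(spec3, ou, duration = 600, dt = 1 / 5000,
                              seed = seed)
write_trace(rel$trace, "scratch/relaxed_trace.tsv")
message("relaxed trace: 600 s at 5 kHz, ",
        length(rel$truth$switch_times), " state switches")

# protein-free recording of the same tether (the closed-duplex span used
# to fix the global noise parameters before any RNP is introduced)
base <- simulate_relaxed_trace(state_spec("C", 0, tether = tether), ou,
                               duration = 60, dt = 1 / 5000, seed = seed + 9L)
write_trace(base$trace, "scratch/baseline_relaxed.tsv")

## torque-driven assay: two-state C <-> I with twist-dependent rates
specR <- state_spec(c("C", "I"), c(0, 7),
                    k0 = c("C->I" = 0.1, "I->C" = 0.1 * exp(3)),
                    barrier_frac = 0.4, tether = tether)
rp <- ramp_profile(low_turns = -5, high_turns = 7.5, rate_rpm = 3)
cal <- simulate_ramp_trace(state_spec("C", 0, tether = tether), ou, rp,
                           duration = 300, dt = 1 / 5000, seed = seed + 1L)
write_trace(cal$trace, "scratch/calibration_ramp.tsv")
ramp <- simulate_ramp_trace(specR, ou, rp, duration = 3000, dt = 1 / 5000,
                            seed = seed + 2L)
write_trace(ramp$trace, "scratch/ramp_trace.tsv")
message("ramp trace: 3000 s (six ramp cycles), ",
        length(ramp$truth$switch_times), " state switches")

## cleavage time courses (fractions on the 7-point quench grid)
slow <- simulate_cleavage_timecourse(A = 0.55, kobs_per_min = 0.01,
                                     noise_sd = 0.02, n_reps = 3,
                                     seed = seed + 3L)
fast <- simulate_cleavage_timecourse(A = 0.85, kobs_per_min = 0.28,
                                     noise_sd = 0.02, n_reps = 3,
                                     seed = seed + 4L)
write_table_tsv(slow, "results/cleavage_wt.tsv")
write_table_tsv(fast, "results/cleavage_variant.tsv")
message("cleavage time courses written (wild-type-like and optimized variant)")
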