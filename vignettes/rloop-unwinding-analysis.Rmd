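---
title: "Stepwise DNA-unwinding kinetics from rotor-bead tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise DNA-unwinding kinetics from rotor-bead tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aurbt)
```

## The measurement and its model

Gold rotor-bead tracking (AuRBT) reports the twist of a stretched DNA
tether at base-pair resolution: a gold nanosphere attached to the DNA
rotates as the duplex under it changes its helical twist. When an
RNA-guided endonuclease forms an R-loop, guide-RNA/DNA base pairing
displaces the non-target strand and locally unwinds the duplex. The
rotor angle therefore steps between discrete levels: a closed duplex C
(0 bp unwound), a partially unwound intermediate I (~7 bp), and a fully
unwound open state O (~14 bp), with occasional short excursions beyond O
(labelled O'). Cumulative rotor angle in turns converts to base pairs
unwound through the B-DNA helicity h = 10.5 bp/turn.

`aurbt` implements the full analysis chain for two assay geometries and
a synthetic-trajectory generator that emulates both, so every stage can
be validated against known ground truth:

1. **Torsionally relaxed assay** — the tether carries a free swivel; the
   rotor mean tracks `x/h` turns for `x` bp unwound. Analysis:
   change-point segmentation, state assignment, transition rates,
   equilibrium free energies.
2. **Torque-driven assay** — the tether is torsionally constrained and
   the magnets impose a twist ramp. Torque is read out across a
   calibrated transducer segment, converted to base pairs unwound, and
   kinetics are resolved as a function of imposed twist.
3. **Bulk cleavage kinetics** — gel-quantified cleaved fractions fit to
   a mono-exponential.

## Observation model and segmentation

Rotor-angle fluctuations about a state mean are modeled as a stationary
Ornstein-Uhlenbeck (OU) process, parameterized by the relaxation time
`tau_c` (s) and stationary SD `sigma` (turns); the physical drag
coefficient never enters. At a fixed sampling interval `dt` the exact
discretization is an AR(1) recursion with coefficient
`a = exp(-dt/tau_c)` and innovation SD `sigma * sqrt(1 - a^2)`. The
generator applies this recursion with the mean relaxing toward the
current state's level, so a state switch produces an exponential
approach over `tau_c` rather than an instantaneous jump — which is also
exactly what the segmentation model assumes.

Global noise parameters are fixed once per tether from a protein-free
baseline recording (`estimate_ou_params()`, lag-1 autocorrelation and
stationary variance); the only free parameters during segmentation are
the per-dwell mean and the change-point times. The AR(1) whitening turns
the OU likelihood into independent Gaussian innovations, so penalized
maximum-likelihood segmentation reduces to least-squares change-in-mean
on the whitened series. `segment_trace()` solves this exactly with a
pruned optimal-partitioning dynamic program (PELT, implemented in C++);
an exhaustive, independently-implemented dynamic program
(`oracle_segment()`, instances up to 2000 samples and 3 change points)
verifies optimality in the test suite. Binary segmentation is *not*
used.

Numerical conventions worth stating:

* **Penalty.** Default `2 * log(n)` per change point (BIC-style: one
  mean plus one breakpoint per extra segment). No threshold is inherent
  to the method; the penalty is a configuration choice and is echoed in
  every pipeline report.
* **Cross-boundary innovation.** The innovation straddling a change
  point is assigned to the later segment in the search cost. Reported
  dwell means exclude it (conditional ML on interior innovations), so a
  noiseless step yields exact means.
* **Minimum dwell.** 5 samples by default; prevents single-sample
  spikes from becoming segments.
* **Decimation.** Traces may be decimated before segmentation
  (default x10 from 5 kHz). Subsampling an exact-discretization OU
  process leaves `tau_c` and `sigma` unchanged, so no parameter
  adjustment is needed.

## State assignment and equilibrium kinetics

Dwell levels (bp) are assigned to states by a one-dimensional
fixed-point iteration: centers are lifetime-weighted mean unwinding
values, boundaries are arithmetic means of adjacent centers, and a dwell
exactly on a boundary goes to the lower state. Because the assay's
states are known a priori, user-supplied initial centers (0, 7, 14 bp)
are preferred; quantile-spread initialization is the fallback. Adjacent
same-state dwells are merged (lifetime-weighted means; merging conserves
total lifetime and per-state weighted means exactly), and all levels are
zeroed so the predominant closed state sits at 0 bp. If the
minimum-center state is not the most occupied, the package warns and
still zeroes to the minimum-center state. O' excursions (beyond the
mirror point of the top boundary about the top center) can be split off;
they are excluded from C/I/O kinetics by default but retained in
occupancy histograms (0.5-bp bins, lifetime-weighted, normalized to 1).

Transition rates divide the number of i -> j transitions by the total
time in state i, counting only after the first transition event: the
first dwell and everything before it are excluded from counts and
occupancy, while the final right-censored dwell contributes occupancy
but no exit. No censoring correction is applied (the bias is
second-order when events are many); the choice is switchable
(`drop_first`). Standard errors assume Poisson transition statistics,
`se = sqrt(N)/T`, so `se/rate = 1/sqrt(N)` exactly. From the rates:
`K_ij = k_ij/k_ji`, `dG_ij = -ln K_ij` (kBT), and display-level barrier
heights `-ln k_ij` against an implicit 1/s attempt frequency — these are
not absolute activation energies and are documented as such. Landscapes
place wells at the lifetime-weighted centers with cumulative `dG` along
C -> I -> O; direct C <-> O transitions, if detected, are reported but
excluded from the landscape path.

## Torque-driven analysis

With the tether torsionally constrained, torque is the transducer
deflection times its stiffness, `tau = kappa_t_turn * (theta - psi)`,
with the transducer stiffness 0.26 pN nm/rad and `kappa_t_turn = 2 pi
kappa_t_rad` for angles in turns. The magnet zero offset is a hardware
calibration and must be supplied (`zero_offset_turns`; zero for
synthetic data). The full-tether stiffness comes from the slope of the
torque-twist line over closed-duplex spans, and base pairs unwound
follow from `dtheta0(bp) = h (tau - tau_B) / (2 pi kappa_rad)` with
`tau_B = kappa_turn * theta`. The generator and the read-out are exact
algebraic inverses: a noiseless round trip reproduces the hidden
unwinding to machine precision, which the tests assert.

Kinetics are binned by imposed twist (default width 0.5 turns, a
configuration choice — occupancy accrues per sample at the instantaneous
twist; each transition counts in the bin of the twist at the transition
time, while dwell-onset twist is recorded separately for display). Any
(bin, pair) with fewer than 3 transitions is excluded. The
twist-dependence fits are weighted least squares of

* `ln K_ij(theta) = beta kappa_turn dtheta_ij theta - beta dG_ij(0)`
  (weights from `se_lnK = sqrt(1/N_ij + 1/N_ji)`), giving the
  equilibrium twist change `dtheta_ij` and zero-twist free energy;
* `ln k_ij(theta) = beta kappa_turn dtheta+_ij theta + ln k_ij(0)` over
  an approximately linear region, giving the transition-state position
  as the fraction `dtheta+_ij / dtheta_ij` between the wells.

The linear region may be supplied explicitly or selected automatically
(largest contiguous bin run shrunk from the worse-fitting end while the
weighted R-squared is below 0.8). When the underlying twist dependence
is shallow relative to the Poisson noise, the automatic rule can retreat
to short, noise-dominated runs; for data generated by the package's own
exponential rate law — which is globally linear in log space — the full
ramp range is the appropriate configured region, and the analysis
drivers use it. Twist-dependent landscapes place well energies at
`dG_ij(theta) = dG_ij(0) - slope_lnK * theta` cumulated along the state
order; well x-positions use the lifetime-weighted unwinding levels
(fitted `dtheta_ij` do not reliably track physical unwinding
differences, so they are used only for the fractional barrier
placement).

A note on units: the twist-energy coupling multiplies `kappa_turn = 2 pi
kappa_rad` by angles in turns on both the generative and the fitting
side. This single consistent convention makes parameter-recovery round
trips exact in expectation; the recovered `dtheta_ij` should be read as
model parameters in this convention rather than as literal physical
twist changes (the fractional barrier position, a ratio of slopes, is
convention-free).

## The synthetic generator as the test bed

`simulate_state_path()` draws a continuous-time Markov switching path
with twist-dependent rates `k_ij(theta) = k_ij(0) exp(beta kappa_turn
dtheta+_ij theta)`; detailed balance is built in by constraining the
reverse transition-state twist `dtheta+_ji = dtheta+_ij - dtheta_ij`, so
`ln K_ij` is exactly linear in twist with slope `beta kappa_turn
dtheta_ij`. Time-inhomogeneous switching during ramps is simulated
exactly by thinning against the supremum of each rate over the twist
range visited (the rate law is monotone in twist, so the supremum sits
at a range endpoint); non-finite rates over the visited range are
rejected with the offending pair named.

Default study conditions: 5 kHz sampling at 5 pN tension; relaxed-mode
states at 0/7/14 bp with rates 0.2, 0.5, 0.1, 0.3 /s (C->I, I->C, I->O,
O->I); ramp mode between +7.5 and -5 turns at 3 RPM with a two-state
C <-> I model (`dG(0) = 3` kBT, barrier fraction 0.4, `k_CI(0) =
0.1`/s); transducer stiffness 0.26 pN nm/rad; full-tether stiffness
0.4 pN nm/rad (torsional modulus ~440 pN nm^2 over a ~1.1 um tether);
5-kb tether; kBT = 4.114 pN nm. The OU parameters of an 80-nm rotor are
not published for this geometry; the defaults `tau_c = 5` ms and `sigma
= 0.05` turns are plausible for a bead of that size and are fully
configurable — parameter-recovery results quoted in the tests are
conditional on them. Cleavage time courses use the 7-point quench grid
(0.5-120 min) with 3 replicates and Gaussian noise (SD 0.02) clipped to
[0, 1], since gel fractions are bounded.

What the generator deliberately does *not* emulate: bead-tracking
localization noise and its spectral shape, drift, torque-dependent
tether extension, plectoneme buckling, photophysics, or the magnet-angle
software delay (negligible at 3 RPM). Passing tests therefore
demonstrate correctness of the inference chain under the stated
stochastic model, not robustness to every instrumental artifact.

## Cleavage fits

`fit_monoexp()` fits `Y = A (1 - exp(-kobs t))` per replicate by
bounded Levenberg-Marquardt least squares, `A` in (0, 1.05] (slightly
above 1 to tolerate noise at saturation) and `kobs >= 0`, reporting
mean +/- SD across replicates. Initial guesses are `A0 = max(Y)` and
`kobs0 = log(2)/t_half` by linear interpolation. `A` is left free rather
than fixed at 1 for weakly cleaving samples, and flat-at-zero replicates
are flagged with `kobs = 0` and an unidentifiable amplitude. Fold
changes between variants propagate the replicate SDs to first order.

## Worked example

```{r example, eval = FALSE}
tether <- tether_spec(length_bp = 5000, kappa_rad = 0.4)
spec <- state_spec(c("C", "I", "O"), c(0, 7, 14),
                   k0 = c("C->I" = 0.2, "I->C" = 0.5,
                          "I->O" = 0.1, "O->I" = 0.3), tether = tether)
ou <- ou_params(tau_c = 5e-3, sigma = 0.05)
sim <- simulate_relaxed_trace(spec, ou, duration = 600, seed = 1)

report <- run_pipeline(list(mode = "relaxed", input_object = sim$trace,
                            out_dir = "out", ou = ou, decimate = 10,
                            state_centers = c(0, 7, 14)))
report$state_model$centers_bp   # ~0, 7, 14
report$thermo                    # K, dG (kBT), barriers per adjacent pair
```

The numbered scripts under `analysis/` run the complete workflow
(simulate; relaxed kinetics; torque-driven twist analysis; cleavage
fits) and write their tables under `results/`.

## Problem sizes and limitations

The validation suite segments relaxed traces of 2000 s at 5 kHz
(decimated x10 for analysis, i.e. one million samples) and twist ramps
of 6000 s; the exhaustive oracle is run on instances up to 2000 samples
with up to 3 change points. These sizes give a few hundred transitions
per pair — enough that Poisson errors, not model mismatch, dominate the
recovery tolerances.

Known limitations: missed dwells shorter than the minimum dwell length
bias rates downward at the fastest exits (second-order at the default
conditions, and visible only at the extreme twist bins of steep ramps);
the occupancy denominator includes the right-censored final dwell
without correction; barrier heights are display-level quantities; and
drift or slowly varying baselines are not modeled — a miscalibrated
tether stiffness shows up as a slow residual drift in the unwinding
series that can split long dwells (harmless after merging, but worth
checking via the stiffness fit's intercept).
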