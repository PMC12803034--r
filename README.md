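# aurbt — rotor-bead tracking analysis of stepwise DNA unwinding

`aurbt` analyzes gold rotor-bead tracking (AuRBT) trajectories of
RNA-guided R-loop formation, the single-molecule assay in which a gold
nanosphere's rotation reports DNA twist at base-pair resolution. R-loop
formation by compact RNA-guided endonucleases proceeds through discrete
unwinding states — closed duplex (C, 0 bp), a partially unwound
intermediate (I, ~7 bp), and a fully unwound open state (O, ~14 bp) —
and the package turns raw rotor-angle time series into the kinetics and
energetics of those steps. It is aimed at single-molecule biophysicists
who want a scriptable, tested alternative to ad-hoc trace analysis.

What it computes:

* **Segmentation.** Change points in the rotor angle under an
  Ornstein–Uhlenbeck observation model with globally fixed noise
  parameters (`tau_c`, `sigma`) and free per-dwell means, solved exactly
  by a penalized optimal-partitioning dynamic program (PELT, C++ core),
  with an exhaustive oracle for validation.
* **State kinetics.** Dwells scored into C/I/O by lifetime-weighted
  clustering (boundaries at arithmetic means of adjacent centers),
  merged, zeroed to the closed state; transition rates
  `k_ij = N_ij / T_i` with Poisson errors, counted after the first
  transition event; occupancy histograms with 0.5-bp bins.
* **Energetics.** `K_ij = k_ij/k_ji`, `ΔG_ij = −kBT ln K_ij`, barrier
  heights `−kBT ln k_ij`, assembled into free-energy landscapes along
  C → I → O.
* **Torque-driven mode.** Torque from the magnet/rotor angle difference
  `τ = κ_t(θ − ψ)` (transducer stiffness 0.26 pN nm/rad), tether
  stiffness from the torque–twist slope, base pairs unwound
  `Δθ0 = 10.5 (τ − τ_B)/(2πκ)`, twist-binned rates (bins with < 3
  transitions excluded), and weighted linear fits
  `ln K_ij = βκΔθ_ij θ − βΔG_ij(0)` and
  `ln k_ij = βκΔθ‡_ij θ + ln k_ij(0)` that yield twist-dependent
  landscapes (e.g. at −5 turns, ~1% negative supercoiling on a 5-kb
  tether).
* **Cleavage kinetics.** Mono-exponential fits `Y = A(1 − e^{−kobs t})`
  per replicate with bounded nonlinear least squares, and rate fold
  changes between variants.
* **Synthetic data.** A generator (hidden-state continuous-time Markov
  switching + exact-discretization OU noise, twist ramps, cleavage time
  courses) with recorded ground truth, used throughout the tests.

## Worked example

The numbered drivers under `analysis/` run the full workflow:

```sh
Rscript analysis/01_simulate.R          # synthetic traces -> scratch/, tables -> results/
Rscript analysis/02_relaxed_kinetics.R  # equilibrium C/I/O kinetics
Rscript analysis/03_torque_twist.R      # torque, twist bins, linear fits, landscapes
Rscript analysis/04_cleavage.R          # mono-exponential fits, fold change
```

`02_relaxed_kinetics.R` segments a 600-s relaxed trace (5 kHz, decimated
×10), scores states against centers (0, 7, 14) bp and prints:

```
baseline OU fit: tau_c = 5.04 ms, sigma = 0.050 turns

state centers (bp): 0.00 7.00 14.01
  from to  n occupancy_s     rate_s       se_s
1    I  C 80     153.316 0.52179812 0.05833880
3    C  I 80     389.692 0.20529033 0.02295216
4    O  I 16      49.664 0.32216495 0.08054124
6    I  O 17     153.316 0.11088210 0.02689286

free energies along C -> I -> O (kBT):
  from to         K    dG_kBT    se_lnK
1    C  I 0.3934287 0.9328555 0.1581139
2    I  O 0.3441780 1.0665962 0.3483153
```

The recovered centers sit on the generator's 0/7/14-bp levels and every
rate is within its Poisson error of the simulated truth (0.2, 0.5, 0.1,
0.3 /s): unwinding is stepwise and uphill at zero twist. The
torque-driven driver then reports, for a C↔I ramp simulated with
ΔG(0) = 3 kBT and barrier fraction 0.4:

```
C<->I twist fit: dtheta = -0.699 turns (7.3 bp), dG(0) = 3.16 kBT,
  barrier fraction 0.39 (transition state 39% of the way to I)

At -5 turns the intermediate well drops by 2.1 kBT relative
to zero twist: negative supercoiling stabilizes the unwound states.
```

and the cleavage driver prints `fold change in kobs: 23.8 +/- 1.0` for
an optimized variant (kobs = 0.266/min) against a slow wild-type-like
enzyme (0.011/min).

See `vignettes/rloop-unwinding-analysis.Rmd` for the model, parameter
conventions, and design choices.

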