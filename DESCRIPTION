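Package: aurbt
Title: Rotor-Bead Tracking Analysis of Stepwise DNA Unwinding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gold rotor-bead tracking (AuRBT)
    trajectories of RNA-guided DNA unwinding. Detects dwells in rotor-angle
    time series by penalized change-point segmentation under an
    Ornstein-Uhlenbeck noise model, assigns dwells to discrete R-loop states
    (closed, intermediate, open), estimates transition rates with Poisson
    errors, and reconstructs free-energy landscapes at zero and imposed
    twist. Torque-driven mode converts magnet and rotor angle differences to
    torque and base pairs unwound, bins kinetics by imposed twist, and fits
    the exponential twist-dependence of rates and equilibrium constants.
    Includes a synthetic-trajectory generator (hidden-state switching plus
    exact-discretization Ornstein-Uhlenbeck noise) and mono-exponential
    fitting of bulk cleavage time courses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
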