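#' Tether specification
#'
#' Mechanical and thermodynamic constants of a torsionally constrained DNA
#' tether as used in rotor-bead tracking: contour length in base pairs,
#' B-DNA helicity, full-tether torsional stiffness, the stiffness of the
#' angular transducer segment, and the thermal energy.
#'
#' @param length_bp tether length N in base pairs.
#' @param helicity h, base pairs per helical turn (B-DNA: 10.5).
#' @param kappa_rad full-tether torsional stiffness, pN nm/rad (slope of the
#'   torque-twist curve).
#' @param kappa_t_rad transducer-segment torsional stiffness, pN nm/rad.
#' @param kBT thermal energy in pN nm (4.114 at 25 C).
#' @param tension_pN stretching force metadata, pN.
#' @return an object of class `tether_spec`.
#' @export
tether_spec <- function(length_bp = 5000, helicity = 10.5, kappa_rad = 0.4,
                        kappa_t_rad = 0.26, kBT = 4.114, tension_pN = 5) {
  x <- list(length_bp = length_bp, helicity = helicity, kappa_rad = kappa_rad,
            kappa_t_rad = kappa_t_rad, kBT = kBT, tension_pN = tension_pN)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("tether_spec: '", nm, "' must be a single positive number")
  }
  if (helicity < 10 || helicity > 11)
    stop("tether_spec: helicity must lie in [10, 11] bp/turn")
  structure(x, class = "tether_spec")
}

#' @export
print.tether_spec <- function(x, ...) {
  cat(sprintf(
    "DNA tether: %d bp (Lk0 = %.1f turns), kappa = %.3g pN nm/rad,\n  transducer %.3g pN nm/rad, kBT = %.3f pN nm, %.1f pN tension\n",
    x$length_bp, lk0(x), x$kappa_rad, x$kappa_t_rad, x$kBT, x$tension_pN))
  invisible(x)
}

# stiffness per turn (torque in pN nm for angles in turns)
kappa_turn <- function(tether) 2 * pi * tether$kappa_rad
kappa_t_turn <- function(tether) 2 * pi * tether$kappa_t_rad
beta_kBT <- function(tether) 1 / tether$kBT

#' Relaxed linking number of a tether
#'
#' `Lk0 = N / h`: turns of helix in the relaxed tether, the denominator of
#' twist density.
#'
#' @param tether a [tether_spec()].
#' @return relaxed linking number in turns.
#' @export
lk0 <- function(tether) tether$length_bp / tether$helicity

#' Ornstein-Uhlenbeck noise parameters
#'
#' Rotor-angle fluctuations about a state-dependent mean are modeled as a
#' stationary OU process, parameterized by its angular relaxation time and
#' stationary standard deviation (the physical drag coefficient is never
#' needed in this parameterization).
#'
#' @param tau_c relaxation time, s.
#' @param sigma stationary standard deviation, turns.
#' @return an object of class `ou_params`.
#' @export
ou_params <- function(tau_c = 5e-3, sigma = 0.05) {
  if (!is.finite(tau_c) || tau_c <= 0) stop("ou_params: tau_c must be > 0")
  if (!is.finite(sigma) || sigma < 0) stop("ou_params: sigma must be >= 0")
  structure(list(tau_c = tau_c, sigma = sigma), class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat(sprintf("OU noise: tau_c = %.3g s, sigma = %.3g turns\n",
              x$tau_c, x$sigma))
  invisible(x)
}

#' Hidden-state kinetic specification for R-loop formation
#'
#' Defines the ordered unwinding states (e.g. closed C at 0 bp, intermediate
#' I at ~7 bp, open O at ~14 bp), the zero-twist rate constants between
#' adjacent states, and the twist coupling of each transition. Under the
#' sign convention used here, unwinding by `x` bp absorbs `x/h` turns of
#' helical twist, so the equilibrium-twist change of transition i -> j is
#' `dtheta_ij = -(x_j - x_i)/h` turns (negative for unwinding) and ln K
#' grows as imposed twist becomes more negative. Rates follow the
#' exponential twist dependence
#' `k_ij(theta) = k_ij(0) * exp(beta * kappa_turn * dtheta_dagger_ij * theta)`
#' with the transition-state twist change `dtheta_dagger_ij = f_ij *
#' dtheta_ij` set by the barrier fraction `f_ij` in `[0, 1]`; the reverse
#' transition-state change is `dtheta_dagger_ji = dtheta_dagger_ij -
#' dtheta_ij`, which enforces that `ln K_ij(theta)` is linear in theta with
#' slope `beta * kappa_turn * dtheta_ij` (detailed-balance consistency).
#'
#' @param labels ordered state names, e.g. `c("C", "I", "O")`.
#' @param unwinding_bp base pairs unwound per state, non-negative and
#'   strictly increasing.
#' @param k0 named numeric vector of zero-twist rates in 1/s for adjacent
#'   transitions, names like `"C->I"`; both directions of each adjacent pair
#'   required.
#' @param barrier_frac named numeric vector (names like `"C->I"`, one per
#'   adjacent forward transition) of barrier fractions in `[0, 1]`;
#'   recycled scalar allowed. Default 0.4.
#' @param tether a [tether_spec()] supplying helicity and stiffness.
#' @return an object of class `state_spec` with a `transitions` data frame
#'   (columns `from`, `to`, `k0`, `dtheta_turns`, `dtheta_dagger_turns`).
#' @export
state_spec <- function(labels, unwinding_bp, k0, barrier_frac = 0.4,
                       tether = tether_spec()) {
  stopifnot(length(labels) == length(unwinding_bp), length(labels) >= 1L)
  if (any(unwinding_bp < 0) || any(diff(unwinding_bp) <= 0) && length(labels) > 1L)
    stop("state_spec: unwinding_bp must be non-negative and strictly increasing")
  n <- length(labels)
  h <- tether$helicity
  trans <- NULL
  if (n > 1L) {
    fwd <- paste0(labels[-n], "->", labels[-1])
    rev <- paste0(labels[-1], "->", labels[-n])
    need <- c(fwd, rev)
    if (!all(need %in% names(k0)))
      stop("state_spec: k0 must name all adjacent transitions: ",
           paste(setdiff(need, names(k0)), collapse = ", "))
    if (any(k0 < 0)) stop("state_spec: rates must be non-negative")
    if (length(barrier_frac) == 1L && is.null(names(barrier_frac)))
      barrier_frac <- setNames(rep(barrier_frac, n - 1L), fwd)
    if (!all(fwd %in% names(barrier_frac)))
      stop("state_spec: barrier_frac must name every forward transition")
    if (any(barrier_frac < 0 | barrier_frac > 1))
      stop("state_spec: barrier fractions must lie in [0, 1]")
    dth <- -(unwinding_bp[-1] - unwinding_bp[-n]) / h  # turns, negative
    ddag_f <- barrier_frac[fwd] * dth
    ddag_r <- ddag_f - dth
    trans <- data.frame(
      from = c(labels[-n], labels[-1]),
      to = c(labels[-1], labels[-n]),
      k0 = as.numeric(k0[c(fwd, rev)]),
      dtheta_turns = c(dth, -dth),
      dtheta_dagger_turns = as.numeric(c(ddag_f, ddag_r)),
      stringsAsFactors = FALSE)
  }
  structure(list(labels = labels, unwinding_bp = unwinding_bp,
                 transitions = trans, tether = tether),
            class = "state_spec")
}

#' @export
print.state_spec <- function(x, ...) {
  cat("R-loop state model:\n")
  cat("  states:", paste(sprintf("%s (%g bp)", x$labels, x$unwinding_bp),
                         collapse = ", "), "\n")
  if (!is.null(x$transitions)) {
    cat("  transitions at zero twist:\n")
    with(x$transitions,
         cat(sprintf("    %s->%s  k0 = %.4g /s  dtheta = %.4g  dtheta+ = %.4g turns\n",
                     from, to, k0, dtheta_turns, dtheta_dagger_turns), sep = ""))
  }
  invisible(x)
}

#' Twist-dependent transition rates of a state model
#'
#' Evaluates `k_ij(theta) = k_ij(0) exp(beta kappa_turn dtheta_dagger_ij
#' theta)` for every transition in the model.
#'
#' @param spec a [state_spec()].
#' @param theta imposed twist in turns (scalar or vector).
#' @return if `theta` is scalar, a data frame of transitions with a `rate`
#'   column; otherwise a matrix with one row per transition and one column
#'   per theta.
#' @export
transition_rates_at <- function(spec, theta) {
  tr <- spec$transitions
  if (is.null(tr)) stop("transition_rates_at: single-state model has no transitions")
  bk <- beta_kBT(spec$tether) * kappa_turn(spec$tether)
  rates <- outer(seq_len(nrow(tr)), seq_along(theta), function(i, j)
    tr$k0[i] * exp(bk * tr$dtheta_dagger_turns[i] * theta[j]))
  if (length(theta) == 1L) {
    tr$rate <- rates[, 1L]
    tr
  } else rates
}

#' Analytic equilibrium ratio of a transition pair
#'
#' `K_ij(theta) = k_ij(theta)/k_ji(theta)`, evaluated in closed form from
#' the model; equals `K_ij(0) * exp(beta kappa_turn dtheta_ij theta)`.
#'
#' @param spec a [state_spec()].
#' @param from,to state labels of the ordered pair.
#' @param theta imposed twist, turns.
#' @return numeric K values, same length as `theta`.
#' @export
equilibrium_ratio_at <- function(spec, from, to, theta = 0) {
  tr <- spec$transitions
  i <- which(tr$from == from & tr$to == to)
  j <- which(tr$from == to & tr$to == from)
  if (length(i) != 1L || length(j) != 1L)
    stop("equilibrium_ratio_at: pair ", from, "<->", to, " not in model")
  bk <- beta_kBT(spec$tether) * kappa_turn(spec$tether)
  (tr$k0[i] / tr$k0[j]) * exp(bk * tr$dtheta_turns[i] * theta)
}
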