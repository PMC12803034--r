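#' Fraction cleaved from per-lane band intensities
#'
#' Cleavage extent per lane is the cleaved-product signal divided by the
#' total lane signal.
#'
#' @param intensities data frame with columns `time_min`, `replicate`,
#'   `band`, `intensity`; the band named `product_band` is the cleaved
#'   product, all bands in a lane sum to the total.
#' @param product_band name of the product band (default "product").
#' @return data frame with `time_min`, `replicate`, `fraction`.
#' @export
fraction_cleaved <- function(intensities, product_band = "product") {
  if (any(intensities$intensity < 0))
    stop("fraction_cleaved: negative intensities")
  tot <- stats::aggregate(intensity ~ time_min + replicate,
                          data = intensities, FUN = sum)
  prod <- intensities[intensities$band == product_band, , drop = FALSE]
  out <- merge(prod[, c("time_min", "replicate", "intensity")], tot,
               by = c("time_min", "replicate"),
               suffixes = c("_product", "_total"))
  if (any(out$intensity_total <= 0))
    stop("fraction_cleaved: zero total lane signal")
  data.frame(time_min = out$time_min, replicate = out$replicate,
             fraction = out$intensity_product / out$intensity_total)
}

#' Mono-exponential fit of cleavage time courses
#'
#' Fits `Y = A (1 - exp(-kobs t))` to each replicate by bounded
#' Levenberg-Marquardt nonlinear least squares (`A` in `(0, 1.05]` to
#' tolerate noise at saturation, `kobs >= 0`), then reports the mean and SD
#' of the per-replicate estimates. Initial guesses: `A0` is the maximum
#' observed fraction; `kobs0 = log(2) / t_half` with the half-maximum time
#' obtained by linear interpolation. Replicates whose fit does not converge
#' (or that never rise above the noise, leaving `A` unidentifiable) are
#' flagged and excluded from the mean with a warning.
#'
#' @param tc data frame with `time_min`, `replicate`, `fraction`.
#' @return list of class `cleavage_fit`: `per_replicate` data frame
#'   (`replicate`, `A`, `kobs_per_min`, `converged`), `A_mean`, `A_sd`,
#'   `kobs_mean`, `kobs_sd` (SD only with >= 2 converged replicates),
#'   `n_reps`.
#' @export
fit_monoexp <- function(tc) {
  reps <- sort(unique(tc$replicate))
  per <- do.call(rbind, lapply(reps, function(r) {
    d <- tc[tc$replicate == r, , drop = FALSE]
    d <- d[order(d$time_min), , drop = FALSE]
    if (nrow(d) < 3L) stop("fit_monoexp: replicate ", r, " has < 3 time points")
    A0 <- max(d$fraction)
    ok <- TRUE
    if (A0 <= 0.02) {  # flat at zero: kobs ~ 0, amplitude unidentifiable
      return(data.frame(replicate = r, A = NA_real_, kobs_per_min = 0,
                        converged = FALSE))
    }
    half <- A0 / 2
    ih <- which(d$fraction >= half)[1L]
    t_half <- if (is.na(ih) || ih == 1L) d$time_min[1L] else {
      f0 <- d$fraction[ih - 1L]; f1 <- d$fraction[ih]
      d$time_min[ih - 1L] + (half - f0) / (f1 - f0) *
        (d$time_min[ih] - d$time_min[ih - 1L])
    }
    k0 <- log(2) / max(t_half, min(d$time_min[d$time_min > 0]))
    fit <- tryCatch(
      minpack.lm::nlsLM(fraction ~ A * (1 - exp(-k * time_min)), data = d,
                        start = list(A = min(A0, 1.04), k = k0),
                        lower = c(1e-6, 0), upper = c(1.05, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      ok <- FALSE
      return(data.frame(replicate = r, A = NA_real_, kobs_per_min = NA_real_,
                        converged = FALSE))
    }
    cf <- coef(fit)
    data.frame(replicate = r, A = unname(cf["A"]),
               kobs_per_min = unname(cf["k"]), converged = ok)
  }))
  good <- per[per$converged, , drop = FALSE]
  if (nrow(good) < nrow(per))
    warning("fit_monoexp: ", nrow(per) - nrow(good),
            " replicate(s) flagged (non-convergent or flat) and excluded")
  out <- list(per_replicate = per,
              A_mean = if (nrow(good)) mean(good$A) else NA_real_,
              A_sd = if (nrow(good) >= 2L) sd(good$A) else NA_real_,
              kobs_mean = if (nrow(good)) mean(good$kobs_per_min) else NA_real_,
              kobs_sd = if (nrow(good) >= 2L) sd(good$kobs_per_min) else NA_real_,
              n_reps = nrow(good))
  class(out) <- "cleavage_fit"
  out
}

#' @export
print.cleavage_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential cleavage fit (%d replicates):\n", x$n_reps))
  cat(sprintf("  A    = %.3f", x$A_mean))
  if (!is.na(x$A_sd)) cat(sprintf(" +/- %.3f", x$A_sd))
  cat(sprintf("\n  kobs = %.4g", x$kobs_mean))
  if (!is.na(x$kobs_sd)) cat(sprintf(" +/- %.2g", x$kobs_sd))
  cat(" per min\n")
  invisible(x)
}

#' Fold change between two cleavage rates
#'
#' Ratio of mean observed rates with first-order error propagation from
#' the across-replicate SDs.
#'
#' @param fit_a,fit_b `cleavage_fit` objects (numerator, denominator).
#' @return list: `fold`, `sd` (NA if either input lacks an SD).
#' @export
rate_fold_change <- function(fit_a, fit_b) {
  ka <- fit_a$kobs_mean; kb <- fit_b$kobs_mean
  if (!is.finite(kb) || kb <= 0) stop("rate_fold_change: zero denominator rate")
  if (!is.finite(ka) || ka <= 0) stop("rate_fold_change: zero numerator rate")
  fold <- ka / kb
  sda <- fit_a$kobs_sd; sdb <- fit_b$kobs_sd
  sd_out <- if (is.na(sda) || is.na(sdb)) NA_real_ else
    fold * sqrt((sda / ka)^2 + (sdb / kb)^2)
  list(fold = fold, sd = sd_out)
}
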