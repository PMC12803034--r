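#' Write an AuRBT trace to a tab-separated file
#'
#' Columns `time_s`, `rotor_turns` (and `magnet_turns` in ramp mode) at
#' full precision, preceded by commented `#key\tvalue` metadata lines
#' (`dt`, `mode`, `seed`, and the tether fields), so a written trace reads
#' back losslessly.
#'
#' @param trace an `rbt_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- c(dt = trace$dt, mode = trace$mode, seed = trace$seed,
            unlist(trace$tether))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s\t%s", names(meta),
                     vapply(meta, function(v)
                       if (is.na(suppressWarnings(as.numeric(v)))) as.character(v)
                       else sprintf("%.17g", as.numeric(v)), "")), con)
  df <- data.frame(time_s = sprintf("%.9f", trace$time_s),
                   rotor_turns = sprintf("%.17g", trace$rotor_turns))
  if (!is.null(trace$magnet_turns))
    df$magnet_turns <- sprintf("%.17g", trace$magnet_turns)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an AuRBT trace written by [write_trace()]
#'
#' Validates the metadata against the tether invariants, checks that the
#' time column is uniform to within 1e-9 s, and that the columns match the
#' recorded mode (ramp traces must carry `magnet_turns`).
#'
#' @param path trace file path.
#' @return an `rbt_trace`.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 50L)
  meta_lines <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", meta_lines), "\t", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  need <- c("dt", "mode", "length_bp", "helicity", "kappa_rad",
            "kappa_t_rad", "kBT", "tension_pN")
  if (!all(need %in% names(meta)))
    stop("read_trace: missing metadata keys: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  mode <- meta[["mode"]]
  if (!mode %in% c("relaxed", "ramp"))
    stop("read_trace: unknown mode '", mode, "'")
  tether <- tether_spec(length_bp = as.numeric(meta[["length_bp"]]),
                        helicity = as.numeric(meta[["helicity"]]),
                        kappa_rad = as.numeric(meta[["kappa_rad"]]),
                        kappa_t_rad = as.numeric(meta[["kappa_t_rad"]]),
                        kBT = as.numeric(meta[["kBT"]]),
                        tension_pN = as.numeric(meta[["tension_pN"]]))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("time_s", "rotor_turns") %in% names(df)))
    stop("read_trace: missing columns time_s / rotor_turns")
  if (mode == "ramp" && !"magnet_turns" %in% names(df))
    stop("read_trace: ramp-mode file lacks magnet_turns")
  dt <- as.numeric(meta[["dt"]])
  if (nrow(df) > 1L && max(abs(diff(df$time_s) - dt)) > 1e-9)
    stop("read_trace: non-uniform time step (tolerance 1e-9 s)")
  new_trace(df$time_s, df$rotor_turns,
            if ("magnet_turns" %in% names(df)) df$magnet_turns else NULL,
            dt, mode, tether,
            if ("seed" %in% names(meta)) as.integer(as.numeric(meta[["seed"]]))
            else NA_integer_)
}

#' Write a tab-separated analysis table
#'
#' @param df data frame (dwell table, rate table, twist bins, fits, ...).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated analysis table
#'
#' @param path file path.
#' @return data frame.
#' @export
read_table_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Read a pipeline configuration file
#'
#' Flat key-value configuration in YAML; keys mirror the arguments of
#' [run_pipeline()].
#'
#' @param path YAML file path.
#' @return named list suitable for [run_pipeline()].
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_config: the 'yaml' package is required")
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("read_config: expected a flat key-value mapping")
  cfg
}

default_config <- function() {
  list(decimate = 10L, penalty = NULL, min_dwell_samples = 5L,
       n_states = 3L, state_centers = NULL, bin_width_turns = 0.5,
       zero_offset_turns = 0, baseline_s = NULL, kappa_rad = NULL,
       landscape_thetas = c(0, -5), min_transitions = 3L, oprime = FALSE,
       seed = 1L)
}

validate_config <- function(config, required) {
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("run_pipeline: config is missing required keys: ",
         paste(missing, collapse = ", "))
}

#' Run the full analysis pipeline on a trace or time-course file
#'
#' Orchestrates the stages in assay order. Relaxed mode: estimate OU noise
#' from a baseline span, decimate, segment, score states, merge and zero,
#' count transition rates, derive equilibrium constants, free energies and
#' barrier heights, and build the equilibrium landscape. Ramp mode inserts
#' the torque conversion (torque from magnet/rotor angle difference,
#' tether stiffness, base pairs unwound), bins kinetics by imposed twist,
#' fits the linear twist dependences, and builds landscapes at the
#' requested twists. Cleavage mode fits the mono-exponential model per
#' replicate.
#'
#' Stage outputs are written as tab-separated tables (plus JSON for state
#' models and landscapes) under `out_dir`, and a `report.json` aggregates
#' the headline numbers together with the effective configuration
#' (including every defaulted choice: penalty, bin width, linear region).
#'
#' @param config named list. Required: `mode` ("relaxed", "ramp" or
#'   "cleavage"), `input` (trace file or cleavage TSV; alternatively pass
#'   an `rbt_trace` / data frame as `input_object`), `out_dir`. Optional
#'   keys (with defaults): `decimate` (10), `penalty` (2 log n),
#'   `min_dwell_samples` (5), `n_states` (3) or `state_centers`,
#'   `bin_width_turns` (0.5), `min_transitions` (3), `zero_offset_turns`
#'   (0), `baseline_s` (span of the baseline used for OU estimation; by
#'   default the longest dwell is reused), `ou` (an [ou_params()],
#'   bypassing estimation), `kappa_rad` (tether stiffness override;
#'   default: trace metadata), `landscape_thetas` (c(0, -5)), `oprime`
#'   (FALSE), `seed`.
#' @return the report, invisibly (also written to
#'   `file.path(out_dir, "report.json")`).
#' @export
run_pipeline <- function(config) {
  validate_config(config, c("mode", "out_dir"))
  if (!config$mode %in% c("relaxed", "ramp", "cleavage"))
    stop("run_pipeline: unknown mode '", config$mode, "'")
  if (is.null(config$input) && is.null(config$input_object))
    stop("run_pipeline: config is missing required keys: input")
  cfg <- modifyList(default_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  # paths are excluded from the report echo so identical configurations
  # yield byte-identical reports wherever they are written
  report <- list(mode = cfg$mode,
                 config = cfg[setdiff(names(cfg),
                                      c("input_object", "ou", "input",
                                        "out_dir"))])
  tryCatch({
    if (cfg$mode == "cleavage") {
      tc <- if (!is.null(cfg$input_object)) cfg$input_object else
        read_table_tsv(cfg$input)
      stage <- "fit_monoexp"
      fit <- fit_monoexp(tc)
      write_table_tsv(fit$per_replicate,
                      file.path(cfg$out_dir, "cleavage_fits.tsv"))
      report$cleavage <- list(per_replicate = fit$per_replicate,
                              A_mean = fit$A_mean, A_sd = fit$A_sd,
                              kobs_mean = fit$kobs_mean,
                              kobs_sd = fit$kobs_sd, n_reps = fit$n_reps)
    } else {
      trace <- if (!is.null(cfg$input_object)) cfg$input_object else
        read_trace(cfg$input)
      h <- trace$tether$helicity

      if (cfg$mode == "ramp") {
        stage <- "compute_torque"
        tq <- compute_torque(trace, cfg$zero_offset_turns)
        kappa_rad <- if (!is.null(cfg$kappa_rad)) cfg$kappa_rad else
          trace$tether$kappa_rad
        stage <- "torque_to_unwinding"
        series_bp <- torque_to_unwinding(tq$torque_pNnm, tq$theta_turns,
                                         kappa_rad, h)
        series <- series_bp; units <- "bp"
        theta_fun <- approxfun(tq$time_s, tq$theta_turns, rule = 2)
        report$kappa_rad <- kappa_rad
      } else {
        series <- trace$rotor_turns; units <- "turns"
      }

      stage <- "estimate_ou_params"
      if (!is.null(cfg$ou)) {
        ou <- cfg$ou
        if (cfg$mode == "ramp" && units == "bp") {
          # rotor-angle noise maps onto the unwinding series with gain
          # h * kappa_t / kappa
          gain <- h * trace$tether$kappa_t_rad / kappa_rad
          ou <- ou_params(ou$tau_c, ou$sigma * gain)
        }
      } else {
        bl <- cfg$baseline_s
        if (is.null(bl)) stop("run_pipeline: provide 'ou' or 'baseline_s'")
        sel <- trace$time_s >= bl[1L] & trace$time_s < bl[2L]
        ou <- estimate_ou_params(series[sel], trace$dt)
      }

      stage <- "segment_trace"
      dec <- max(1L, as.integer(cfg$decimate))
      keep <- seq(1L, length(series), by = dec)
      x <- series[keep]
      dt <- trace$dt * dec
      seg <- segment_trace(x, dt, ou, penalty = cfg$penalty,
                           min_dwell_samples = cfg$min_dwell_samples)
      dwells <- seg$dwells
      if (units == "turns") dwells <- dwells_to_bp(dwells, h)

      stage <- "cluster_states"
      model <- cluster_states(dwells, centers = cfg$state_centers,
                              n_states = cfg$n_states)
      stage <- "assign_merge_zero"
      amz <- assign_merge_zero(dwells, model, oprime = cfg$oprime)
      write_table_tsv(amz$dwells, file.path(cfg$out_dir, "dwells.tsv"))
      jsonlite::write_json(
        list(labels = amz$model$labels, centers_bp = amz$model$centers_bp,
             boundaries_bp = amz$model$boundaries_bp,
             offset_bp = amz$offset_bp),
        file.path(cfg$out_dir, "state_model.json"),
        auto_unbox = TRUE, digits = NA)
      stage <- "occupancy_histogram"
      hist <- occupancy_histogram(amz$dwells)
      write_table_tsv(hist, file.path(cfg$out_dir, "occupancy_histogram.tsv"))

      report$ou <- list(tau_c = ou$tau_c, sigma = ou$sigma)
      report$penalty <- if (is.null(cfg$penalty)) 2 * log(length(x)) else cfg$penalty
      report$state_model <- list(labels = amz$model$labels,
                                 centers_bp = amz$model$centers_bp,
                                 boundaries_bp = amz$model$boundaries_bp,
                                 offset_bp = amz$offset_bp)

      stage <- "transition_rates"
      rates <- transition_rates(amz$dwells)
      write_table_tsv(rates, file.path(cfg$out_dir, "rates.tsv"))
      report$rates <- as.list(as.data.frame(rates))
      stage <- "derive_thermodynamics"
      thermo <- derive_thermodynamics(rates, order = amz$model$labels)
      write_table_tsv(thermo, file.path(cfg$out_dir, "thermo.tsv"))
      report$thermo <- as.list(as.data.frame(thermo))
      stage <- "equilibrium_landscape"
      ls0 <- equilibrium_landscape(thermo, amz$model)
      jsonlite::write_json(list(wells = ls0$wells, barriers = ls0$barriers),
                           file.path(cfg$out_dir, "landscape_equilibrium.json"),
                           auto_unbox = TRUE, digits = NA)

      if (cfg$mode == "ramp") {
        stage <- "bin_kinetics_by_twist"
        bins <- bin_kinetics_by_twist(amz$dwells, theta_fun, dt,
                                      bin_width_turns = cfg$bin_width_turns,
                                      min_transitions = cfg$min_transitions)
        write_table_tsv(bins, file.path(cfg$out_dir, "twist_bins.tsv"))
        stage <- "fit_twist_dependence"
        fits <- fit_twist_dependence(bins, trace$tether,
                                     order = amz$model$labels)
        write_table_tsv(fits, file.path(cfg$out_dir, "twist_fits.tsv"))
        report$twist_fits <- as.list(as.data.frame(fits))
        stage <- "twist_landscape"
        lss <- lapply(cfg$landscape_thetas, function(th)
          twist_landscape(fits, amz$model, th))
        names(lss) <- paste0("theta_", cfg$landscape_thetas)
        jsonlite::write_json(
          lapply(lss, function(l) list(theta_turns = l$theta_turns,
                                       wells = l$wells, barriers = l$barriers)),
          file.path(cfg$out_dir, "landscapes_twist.json"),
          auto_unbox = TRUE, digits = NA)
      }
    }
  }, error = function(e) {
    stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
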