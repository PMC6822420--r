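# Structured run configuration: every protocol constant with its default,
# YAML-serializable and hash-stable.

CONFIG_SCHEMA_VERSION <- 1L

#' Run configuration for the cross-over pipeline
#'
#' Aggregates all protocol constants with their study defaults: etCO2 band
#' +/- 2 mmHg, 300-s endpoint window, 2.5-s hold maneuver, 0.01-s sampling,
#' +/-10% %MinVol step on a 25-350% range, RR solver bounds 4-60/min.
#'
#' @param seed master seed for cohort generation and the trial.
#' @param n_patients,ards_n cohort composition.
#' @param etco2_band etCO2 band half-width, mmHg.
#' @param window_s endpoint averaging window, s.
#' @param hold_s hold maneuver duration, s.
#' @param sampling_dt waveform sampling interval, s (fixed at 0.01).
#' @param minvol_step fractional %MinVol protocol step.
#' @param pct_bounds %MinVol range.
#' @param titrate_tol fine titration tolerance, mmHg.
#' @param rr_bounds RR solver bounds, breaths/min.
#' @param delta_p_max inspiratory pressure clamp, cmH2O.
#' @param abg_sd blood-gas PaCO2 measurement SD, mmHg.
#' @param output_dir directory for trial exports.
#' @param cohort a [cohort_params()] object (stored as plain lists in YAML).
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_patients = 20L, ards_n = 10L,
                       etco2_band = 2, window_s = 300, hold_s = 2.5,
                       sampling_dt = 0.01, minvol_step = 0.10,
                       pct_bounds = c(25, 350), titrate_tol = 0.1,
                       rr_bounds = c(4, 60), delta_p_max = 40,
                       abg_sd = 1.5, output_dir = "trial_output",
                       cohort = cohort_params()) {
  if (sampling_dt != WAVEFORM_DT) {
    stop("`sampling_dt` is fixed at 0.01 s (100-Hz recording)",
         call. = FALSE)
  }
  structure(list(schema_version = CONFIG_SCHEMA_VERSION,
                 seed = as.integer(seed), n_patients = as.integer(n_patients),
                 ards_n = as.integer(ards_n), etco2_band = etco2_band,
                 window_s = window_s, hold_s = hold_s,
                 sampling_dt = sampling_dt, minvol_step = minvol_step,
                 pct_bounds = pct_bounds, titrate_tol = titrate_tol,
                 rr_bounds = rr_bounds, delta_p_max = delta_p_max,
                 abg_sd = abg_sd, output_dir = output_dir,
                 cohort = unclass(cohort)),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) ||
      raw$schema_version != CONFIG_SCHEMA_VERSION) {
    stop("unsupported or missing config schema version", call. = FALSE)
  }
  cohort <- do.call(cohort_params,
                    raw$cohort[setdiff(names(raw$cohort), character(0))])
  args <- raw[setdiff(names(raw), c("schema_version", "cohort"))]
  do.call(run_config, c(args, list(cohort = cohort)))
}

#' @rdname run_config
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline from a configuration
#'
#' Generates the cohort, runs the cross-over trial and (optionally) writes
#' the CSV exports and manifest into the configured output directory.
#'
#' @param cfg a [run_config()].
#' @param write logical: write exports to `cfg$output_dir`.
#' @return the [run_crossover_trial()] result, invisibly when writing.
#' @export
run_trial_from_config <- function(cfg, write = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  cohort <- generate_cohort(cfg$n_patients, cfg$ards_n, cfg$seed,
                            params = do.call(cohort_params, cfg$cohort))
  res <- run_crossover_trial(cohort, seed = cfg$seed, abg_sd = cfg$abg_sd,
                             window_s = cfg$window_s, hold_s = cfg$hold_s,
                             etco2_band = cfg$etco2_band,
                             minvol_step = cfg$minvol_step,
                             pct_bounds = cfg$pct_bounds,
                             titrate_tol = cfg$titrate_tol,
                             rr_bounds = cfg$rr_bounds,
                             delta_p_max = cfg$delta_p_max)
  if (write) {
    write_trial_csv(res, cfg$output_dir)
    write_cohort_csv(cohort, file.path(cfg$output_dir, "cohort.csv"))
    invisible(res)
  } else {
    res
  }
}
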