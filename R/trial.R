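# Randomized cross-over trial engine.
#
# Each synthetic patient is ventilated with both adaptive modes in
# randomized order: the last clinically selected minute ventilation is the
# target, the %MinVol loop holds end-tidal CO2 at its baseline value, PEEP
# is kept unchanged, and the endpoints of each phase are measured from a
# simulated 100-Hz waveform covering the final five minutes plus a terminal
# end-inspiratory hold maneuver. Arterial blood-gas sampling noise is drawn
# per patient and mode (never per phase order), so phase order has exactly
# zero effect on any endpoint.

#' Sealed-envelope randomization of the mode sequence
#'
#' A fixed pool of `n/2` "AVM first" and `n/2` "AVM2 first" envelopes is
#' shuffled by the seed.
#'
#' @param rng_seed integer seed.
#' @param n number of patients (even).
#' @return character vector of `"AVM_first"` / `"AVM2_first"`.
#' @export
randomize_sequence <- function(rng_seed, n) {
  if (n < 2 || n %% 2 != 0) stop("`n` must be even", call. = FALSE)
  set.seed(rng_seed)
  sample(rep(c("AVM_first", "AVM2_first"), n / 2))
}

# Measure one mode phase: run the controller loop, simulate the endpoint
# window plus terminal hold, and read every endpoint from the waveform and
# the gas model.
measure_phase <- function(pat, mode, nominal_ve, abg_noise, window_s = 300,
                          hold_s = 2.5, max_steps = 20, ...) {
  cfg <- mode_config(mode = mode, nominal_ve = nominal_ve, ...)
  loop <- run_controller_loop(pat$mech, cfg, peep = pat$baseline$peep,
                              baseline_etco2 = pat$baseline$etco2,
                              max_steps = max_steps)
  set <- loop$settings
  n_breaths <- ceiling((window_s + 10) / (60 / set$rr))
  wave <- simulate_phase(pat$mech, set, n_breaths, terminal_hold = hold_s)
  bm <- breath_metrics(wave)
  wa <- window_average(bm[!bm$has_hold, , drop = FALSE], window = window_s)
  vt <- wa$vt_exp
  rr_meas <- 60 / stats::median(bm$duration_s[!bm$has_hold])
  dp_stat <- driving_pressure_static(wave)
  crs_meas <- static_compliance(vt, as.numeric(dp_stat))
  rce_est <- as.numeric(expiratory_time_constant(wave))
  va_true <- model_alveolar_ventilation(pat$mech, vt, rr_meas)
  gas <- gas_exchange_steady_state(pat$mech, va_true)
  paco2_meas <- gas$paco2 + abg_noise
  pe <- mixed_expired_co2(pat$mech, gas$paco2, vt)
  vd <- bohr_dead_space(paco2_meas, min(pe, paco2_meas), vt)
  va_meas <- alveolar_minute_ventilation(vt, vd, rr_meas)
  data.frame(
    id = pat$id, ards = pat$ards, mode = mode,
    vt_per_kg = vt / pat$mech$pbw, vt_ml = vt,
    delta_p_stat = as.numeric(dp_stat),
    p_insp = set$peep + set$delta_p,
    rr = rr_meas, mp = mechanical_power(wave),
    va = va_meas / 1000, va_true = va_true / 1000,
    paw_mean = mean_airway_pressure(wave),
    crs = crs_meas, rce = rce_est,
    paco2 = paco2_meas, etco2 = loop$gas$etco2,
    pct_minvol = loop$pct_minvol, steps = loop$steps,
    converged = loop$converged, in_band = loop$in_band,
    rr_clamped = loop$flags$rr_clamped, dp_clamped = loop$flags$dp_clamped,
    auto_peep = attr(wave, "auto_peep"))
}

TRIAL_ENDPOINTS <- c("vt_per_kg", "delta_p_stat", "p_insp", "rr", "mp",
                     "va", "paw_mean", "crs", "rce", "paco2")

#' Run the randomized cross-over trial on a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result (even size).
#' @param seed integer seed governing randomization and blood-gas sampling
#'   noise.
#' @param abg_sd arterial blood-gas measurement SD on PaCO2, mmHg.
#' @param window_s endpoint averaging window, s.
#' @param hold_s terminal hold maneuver duration, s.
#' @param max_steps %MinVol adjustment budget per phase.
#' @param ... further arguments passed to [mode_config()] (protocol
#'   constants such as `etco2_band` or `minvol_step`).
#' @return an object of class `trial_result`: `phases` (one row per patient
#'   and mode), `sequences`, `tests` (one [paired_compare()] per endpoint),
#'   `correlations` (tidal volume vs measured compliance per mode),
#'   `failures` and `seed`.
#' @export
#' @examples
#' \donttest{
#' tr <- run_crossover_trial(generate_cohort(4, 2, seed = 7), seed = 7)
#' tr
#' }
run_crossover_trial <- function(cohort, seed, abg_sd = 1.5, window_s = 300,
                                hold_s = 2.5, max_steps = 20, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- length(cohort)
  seqs <- randomize_sequence(seed, n)
  set.seed(seed + 1L)
  abg <- matrix(stats::rnorm(2L * n, 0, abg_sd), nrow = n,
                dimnames = list(NULL, c("AVM", "AVM2")))
  phases <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    pat <- cohort[[i]]
    order <- if (seqs[i] == "AVM_first") c("AVM", "AVM2") else c("AVM2", "AVM")
    rows <- lapply(order, function(mode) {
      tryCatch(
        cbind(measure_phase(pat, mode, nominal_ve = pat$baseline$ve,
                            abg_noise = abg[i, mode], window_s = window_s,
                            hold_s = hold_s, max_steps = max_steps, ...),
              sequence = seqs[i], phase_order = match(mode, order)),
        error = function(e) {
          failures <<- c(failures, sprintf("%s/%s: %s", pat$id, mode,
                                           conditionMessage(e)))
          NULL
        })
    })
    phases[[i]] <- do.call(rbind, rows)
  }
  phases <- do.call(rbind, phases)
  complete <- stats::na.omit(unique(phases$id[duplicated(phases$id)]))
  ph <- phases[phases$id %in% complete, , drop = FALSE]
  a <- ph[ph$mode == "AVM", , drop = FALSE]
  b <- ph[ph$mode == "AVM2", , drop = FALSE]
  b <- b[match(a$id, b$id), , drop = FALSE]
  if (nrow(a) >= 3) {
    tests <- lapply(TRIAL_ENDPOINTS, function(ep) {
      paired_compare(a[[ep]], b[[ep]], label = ep)
    })
    names(tests) <- TRIAL_ENDPOINTS
    correlations <- list(
      AVM = pearson_correlation(a$vt_ml, a$crs),
      AVM2 = pearson_correlation(b$vt_ml, b$crs))
  } else {
    tests <- NULL
    correlations <- NULL
  }
  structure(list(phases = phases, sequences = data.frame(
    id = vapply(cohort, `[[`, "", "id"), sequence = seqs),
    tests = tests, correlations = correlations,
    failures = failures, seed = seed),
    class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  ph <- x$phases
  a <- ph[ph$mode == "AVM", ]
  b <- ph[ph$mode == "AVM2", ]
  cat(sprintf("<trial_result> %d patients, seed %d%s\n",
              length(unique(ph$id)), x$seed,
              if (length(x$failures)) sprintf(" (%d failures)",
                                              length(x$failures)) else ""))
  cat(sprintf("  %-14s %10s %12s %9s\n", "endpoint", "AVM", "AVM2", "p"))
  fmt <- function(v) sprintf("%.1f+/-%.1f", mean(v), stats::sd(v))
  for (ep in TRIAL_ENDPOINTS) {
    p <- if (is.null(x$tests)) NA_real_ else x$tests[[ep]]$p_value
    cat(sprintf("  %-14s %10s %12s %9.2g\n", ep, fmt(a[[ep]]), fmt(b[[ep]]),
                p))
  }
  if (!is.null(x$correlations)) {
    cat(sprintf("  r(VT, Crs): AVM %.2f, AVM2 %.2f\n",
                x$correlations$AVM$r, x$correlations$AVM2$r))
  }
  invisible(x)
}

#' Export a trial result as CSV tables and a JSON manifest
#'
#' Writes `phase_summaries.csv` (one row per patient and mode),
#' `test_table.csv` (one row per endpoint, mode means and the paired test)
#' and `manifest.json` (seed, package version, R version).
#'
#' @param result a `trial_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial_csv <- function(result, dir) {
  stopifnot(inherits(result, "trial_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$phases, file.path(dir, "phase_summaries.csv"),
                   row.names = FALSE)
  ph <- result$phases
  a <- ph[ph$mode == "AVM", ]
  b <- ph[ph$mode == "AVM2", ]
  tab <- do.call(rbind, lapply(TRIAL_ENDPOINTS, function(ep) {
    t <- result$tests[[ep]]
    data.frame(endpoint = ep,
               avm_mean = mean(a[[ep]]), avm_sd = stats::sd(a[[ep]]),
               avm2_mean = mean(b[[ep]]), avm2_sd = stats::sd(b[[ep]]),
               test = if (is.null(t)) NA_character_ else t$test,
               statistic = if (is.null(t)) NA_real_ else t$statistic,
               p_value = if (is.null(t)) NA_real_ else t$p_value)
  }))
  utils::write.csv(tab, file.path(dir, "test_table.csv"), row.names = FALSE)
  manifest <- list(seed = result$seed,
                   n_patients = length(unique(ph$id)),
                   failures = result$failures,
                   package = "adaptivent",
                   version = as.character(utils::packageVersion("adaptivent")),
                   r_version = R.version.string,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
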