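# Closed-loop adaptive ventilation controller.
#
# Each control step maps (target minute ventilation, measured mechanics) to
# a full set of ventilator settings: the mode's selection equation gives RR,
# the tidal volume follows as VE/RR, the I:E rule fixes the inspiratory
# time, and the inspiratory pressure is the one that delivers the target
# tidal volume at the cyclic steady state of the single-compartment plant
# (the volume-targeting servo every adaptive pressure mode runs breath by
# breath). The %MinVol loop then holds end-tidal CO2 at the baseline value:
# the protocol's banded rule (+/-10% per step outside the +/-2 mmHg band)
# brings etCO2 into the band, and a fine proportional titration keeps it
# near the baseline target, which is what equalizes alveolar ventilation
# across mode phases.

#' Mode configuration for the adaptive controller
#'
#' @param mode `"AVM"` (Otis selection) or `"AVM2"` (inspiratory-power
#'   minimization).
#' @param nominal_ve nominal (baseline) minute ventilation, ml/min.
#' @param pct_minvol target minute ventilation as a percentage of nominal.
#' @param rr_bounds solver bounds, breaths/min, within `[4, 60]`.
#' @param delta_p_max inspiratory-pressure clamp above PEEP, cmH2O.
#' @param etco2_band half-width of the protocol's etCO2 target band, mmHg.
#' @param minvol_step fractional %MinVol step of the banded protocol rule.
#' @param pct_bounds admissible %MinVol range.
#' @param titrate_tol stop tolerance of the fine etCO2 titration, mmHg
#'   (`NA` disables titration: the loop then stops anywhere inside the
#'   band).
#' @param ie_te_multiple,ie_ti_frac_min,ie_ti_frac_max AVM I:E rule
#'   parameters, see [ie_rule()].
#' @param ie_fraction_avm2 inspiratory fraction of the AVM2 half-cycle rule.
#' @param ie_te_protect AVM2 expiratory-time protection, in units of `rce`.
#' @return an object of class `mode_config`.
#' @export
mode_config <- function(mode = c("AVM", "AVM2"), nominal_ve,
                        pct_minvol = 100, rr_bounds = c(4, 60),
                        delta_p_max = 40, etco2_band = 2,
                        minvol_step = 0.10, pct_bounds = c(25, 350),
                        titrate_tol = 0.1, ie_te_multiple = 3,
                        ie_ti_frac_min = 0.25, ie_ti_frac_max = 1 / 3,
                        ie_fraction_avm2 = 0.5, ie_te_protect = 2) {
  mode <- match.arg(mode)
  if (nominal_ve <= 0) stop("`nominal_ve` must be positive", call. = FALSE)
  if (pct_minvol <= 0) stop("`pct_minvol` must be positive", call. = FALSE)
  if (delta_p_max <= 0) stop("`delta_p_max` must be positive", call. = FALSE)
  if (rr_bounds[1] < 4 || rr_bounds[2] > 60 || rr_bounds[1] >= rr_bounds[2]) {
    stop("`rr_bounds` must lie within [4, 60]", call. = FALSE)
  }
  structure(list(mode = mode, nominal_ve = nominal_ve,
                 pct_minvol = pct_minvol, rr_bounds = rr_bounds,
                 delta_p_max = delta_p_max, etco2_band = etco2_band,
                 minvol_step = minvol_step, pct_bounds = pct_bounds,
                 titrate_tol = titrate_tol,
                 ie_te_multiple = ie_te_multiple,
                 ie_ti_frac_min = ie_ti_frac_min,
                 ie_ti_frac_max = ie_ti_frac_max,
                 ie_fraction_avm2 = ie_fraction_avm2,
                 ie_te_protect = ie_te_protect),
            class = "mode_config")
}

#' Inspiratory-time rule per mode
#'
#' AVM2 uses half the breath cycle (I:E = 1:1, matching its square-wave
#' power objective), shortened when necessary by the expiratory-time
#' protection of the adaptive-ventilation family: expiration is granted at
#' least `te_protect` expiratory time constants, which at cohort-typical
#' mechanics yields the observed I:E near 1:1.1. AVM aims for an
#' expiratory time of `te_multiple` time constants (near-complete
#' exhalation), with the inspiratory fraction clamped between
#' `ti_frac_min` and `ti_frac_max` of the cycle; the defaults reproduce an
#' I:E near 1:2. Either way the expiratory time is at least
#' `min(3 RCe, 2/3 cycle)` under the default AVM parameters.
#'
#' @param mode `"AVM"` or `"AVM2"`.
#' @param rr respiratory rate, breaths/min.
#' @param rce measured expiratory time constant, s.
#' @param ti_frac_min,ti_frac_max,te_multiple AVM rule parameters.
#' @param avm2_fraction AVM2 inspiratory fraction of the cycle.
#' @param te_protect minimum expiratory time in units of `rce` (AVM2).
#' @return inspiratory time, s.
#' @export
ie_rule <- function(mode, rr, rce, ti_frac_min = 0.25, ti_frac_max = 1 / 3,
                    te_multiple = 3, avm2_fraction = 0.5, te_protect = 2) {
  if (rr <= 0) stop("`rr` must be positive", call. = FALSE)
  cycle <- 60 / rr
  if (mode == "AVM2") {
    min(max(cycle - te_protect * rce, ti_frac_min * cycle),
        avm2_fraction * cycle)
  } else {
    min(max(cycle - te_multiple * rce, ti_frac_min * cycle),
        ti_frac_max * cycle)
  }
}

#' Banded %MinVol adjustment rule
#'
#' The protocol keeps etCO2 within `band` mmHg of its baseline value: above
#' the band the target minute ventilation is raised by `step`, below the
#' band lowered by `step`, inside the band it is left unchanged; the result
#' is confined to `bounds`.
#'
#' @param etco2 current end-tidal CO2, mmHg.
#' @param baseline_etco2 baseline end-tidal CO2, mmHg.
#' @param pct_minvol current %MinVol.
#' @param band band half-width, mmHg.
#' @param step fractional step.
#' @param bounds admissible %MinVol range.
#' @return adjusted %MinVol.
#' @export
#' @examples
#' minvol_adjustment(44, 40, 100) # 110
#' minvol_adjustment(41, 40, 100) # unchanged
minvol_adjustment <- function(etco2, baseline_etco2, pct_minvol,
                              band = 2, step = 0.10, bounds = c(25, 350)) {
  if (any(c(etco2, baseline_etco2, pct_minvol) <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  out <- if (etco2 > baseline_etco2 + band) {
    pct_minvol * (1 + step)
  } else if (etco2 < baseline_etco2 - band) {
    pct_minvol * (1 - step)
  } else {
    pct_minvol
  }
  min(max(out, bounds[1]), bounds[2])
}

# Inspiratory pressure above PEEP that delivers vt_target at the cyclic
# steady state for the given phase durations (volume-targeting servo).
servo_delta_p <- function(mech, vt_target, ti, te) {
  ti_q <- quantize(ti) * WAVEFORM_DT
  te_q <- quantize(te) * WAVEFORM_DT
  unit <- steady_state_volumes(mech, 1, ti_q, te_q)
  vt_target / (unit$v_ei - unit$v0)
}

#' One deterministic control step
#'
#' Computes the ventilator settings the adaptive mode would select from the
#' current %MinVol target and the measured mechanics.
#'
#' @param cfg a [mode_config()].
#' @param mech the plant, a [patient_mechanics()] (used by the
#'   volume-targeting pressure servo).
#' @param mech_measured list with elements `rce` and `crs` (and optionally
#'   `r_insp`) as measured by the ventilator; defaults to the true values.
#' @param pct_minvol current %MinVol (defaults to the configured value).
#' @param peep set PEEP, cmH2O.
#' @return a list: `settings` (a [ventilator_settings()]), `rr_selection`,
#'   `vt_target` and flags `rr_clamped`, `dp_clamped`.
#' @export
controller_step <- function(cfg, mech, peep,
                            mech_measured = list(rce = mech$rce,
                                                 crs = mech$crs,
                                                 r_insp = mech$r_insp),
                            pct_minvol = cfg$pct_minvol) {
  stopifnot(inherits(cfg, "mode_config"), inherits(mech, "patient_mechanics"))
  ve <- pct_minvol / 100 * cfg$nominal_ve
  inp <- rr_selection_input(ve, mech$vda, mech_measured$rce,
                            cfg$rr_bounds[1], cfg$rr_bounds[2])
  sel <- if (cfg$mode == "AVM") select_rr_otis(inp) else select_rr_minpower(inp)
  rr <- sel$rr
  vt_target <- ve / rr
  ti <- ie_rule(cfg$mode, rr, mech_measured$rce,
                ti_frac_min = cfg$ie_ti_frac_min,
                ti_frac_max = cfg$ie_ti_frac_max,
                te_multiple = cfg$ie_te_multiple,
                avm2_fraction = cfg$ie_fraction_avm2,
                te_protect = cfg$ie_te_protect)
  te <- 60 / rr - ti
  dp <- servo_delta_p(mech, vt_target, ti, te)
  dp_clamped <- dp > cfg$delta_p_max
  dp <- min(dp, cfg$delta_p_max)
  list(settings = ventilator_settings(peep = peep, delta_p = dp, rr = rr,
                                      ti = ti),
       rr_selection = sel, vt_target = vt_target,
       rr_clamped = sel$clamped, dp_clamped = dp_clamped)
}

#' Run the %MinVol / etCO2 loop to convergence for one mode phase
#'
#' Iterates [controller_step()], the steady-state gas exchange and the
#' %MinVol adjustment until end-tidal CO2 settles at the baseline target:
#' outside the protocol band the banded rule ([minvol_adjustment()])
#' applies; inside the band a proportional titration (capped at the banded
#' step size) trims etCO2 to within `titrate_tol` of baseline.
#'
#' @param mech a [patient_mechanics()] plant.
#' @param cfg a [mode_config()].
#' @param peep set PEEP, cmH2O (held constant per protocol).
#' @param baseline_etco2 baseline end-tidal CO2 target, mmHg.
#' @param max_steps maximum number of adjustment iterations.
#' @return a list: final `settings`, `pct_minvol`, `gas` (a `gas_state`),
#'   `vt` (delivered, ml), `rr`, `converged`, `in_band`, `steps`
#'   (adjustment steps used), `flags` and a `trace` data frame with one row
#'   per control step (`step, mode, pct_minvol, rr, ti_s, delta_p, etco2`).
#' @export
run_controller_loop <- function(mech, cfg, peep, baseline_etco2,
                                max_steps = 20) {
  stopifnot(inherits(mech, "patient_mechanics"), inherits(cfg, "mode_config"))
  pct <- cfg$pct_minvol
  trace <- vector("list", max_steps + 1L)
  flags <- list(rr_clamped = FALSE, dp_clamped = FALSE)
  converged <- FALSE
  step_out <- NULL
  gas <- NULL
  for (k in seq_len(max_steps + 1L)) {
    step_out <- controller_step(cfg, mech, peep, pct_minvol = pct)
    flags$rr_clamped <- flags$rr_clamped || step_out$rr_clamped
    flags$dp_clamped <- flags$dp_clamped || step_out$dp_clamped
    set <- step_out$settings
    va <- model_alveolar_ventilation(mech, step_out$vt_target, set$rr)
    gas <- gas_exchange_steady_state(mech, va)
    trace[[k]] <- data.frame(step = k, mode = cfg$mode, pct_minvol = pct,
                             rr = set$rr, ti_s = set$ti,
                             delta_p = set$delta_p, etco2 = gas$etco2)
    dev <- gas$etco2 - baseline_etco2
    tol <- if (is.na(cfg$titrate_tol)) cfg$etco2_band else cfg$titrate_tol
    if (abs(dev) <= tol || k > max_steps) {
      converged <- abs(dev) <= tol
      break
    }
    if (abs(dev) > cfg$etco2_band) {
      pct <- minvol_adjustment(gas$etco2, baseline_etco2, pct,
                               band = cfg$etco2_band, step = cfg$minvol_step,
                               bounds = cfg$pct_bounds)
    } else {
      fac <- gas$paco2 / (baseline_etco2 + mech$etco2_gradient)
      fac <- min(max(fac, 1 - cfg$minvol_step), 1 + cfg$minvol_step)
      pct <- min(max(pct * fac, cfg$pct_bounds[1]), cfg$pct_bounds[2])
    }
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  list(settings = step_out$settings, pct_minvol = pct, gas = gas,
       vt = step_out$vt_target, rr = step_out$settings$rr,
       converged = converged,
       in_band = abs(gas$etco2 - baseline_etco2) <= cfg$etco2_band,
       steps = nrow(trace) - 1L, flags = flags, trace = trace)
}

#' @rdname run_controller_loop
#' @param loop a `run_controller_loop()` result.
#' @param path output CSV path for the controller trace.
#' @export
write_controller_trace_csv <- function(loop, path) {
  utils::write.csv(loop$trace, path, row.names = FALSE)
  invisible(path)
}
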