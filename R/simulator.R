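# 100-Hz single-compartment simulator for pressure-controlled ventilation.
#
# Linear one-compartment model with separate inspiratory and expiratory
# resistances. Inspiration: airway pressure steps (optionally with a linear
# rise) from PEEP to PEEP + delta_p and the lung inflates exponentially with
# time constant tau_i = r_insp * crs / 1000. Expiration: passive exponential
# emptying with tau_e = rce. The per-breath volume map is affine in the
# end-expiratory volume, so its cyclic steady state (including trapped
# volume / auto-PEEP when the expiratory time is short) is the fixed point
# of a geometric series and is computed in closed form.

WAVEFORM_DT <- 0.01  # s; the ventilator records at 100 Hz

#' Ventilator settings for one pressure-controlled mode phase
#'
#' @param peep set positive end-expiratory pressure, cmH2O.
#' @param delta_p inspiratory pressure above PEEP, cmH2O (positive).
#' @param rr set respiratory rate, breaths/min.
#' @param ti inspiratory time, s.
#' @param hold_duration end-inspiratory occlusion per breath, s; 0 disables
#'   the hold, otherwise it must lie within 2-3 s and still leave a positive
#'   expiratory time.
#' @param rise_time linear pressurization time, s (0 = ideal square wave).
#' @return an object of class `ventilator_settings`.
#' @export
ventilator_settings <- function(peep, delta_p, rr, ti, hold_duration = 0,
                                rise_time = 0) {
  vals <- c(peep = peep, delta_p = delta_p, rr = rr, ti = ti,
            hold_duration = hold_duration, rise_time = rise_time)
  if (any(!is.finite(vals))) stop("settings must be finite", call. = FALSE)
  if (peep < 0) stop("`peep` must be non-negative", call. = FALSE)
  if (delta_p <= 0) stop("`delta_p` must be positive", call. = FALSE)
  if (rr <= 0 || ti <= 0) stop("`rr` and `ti` must be positive", call. = FALSE)
  if (rise_time < 0 || rise_time > ti) {
    stop("`rise_time` must lie in [0, ti]", call. = FALSE)
  }
  if (hold_duration != 0 && (hold_duration < 2 || hold_duration > 3)) {
    stop("a requested hold must last 2-3 s", call. = FALSE)
  }
  if (ti + hold_duration >= 60 / rr) {
    stop("expiratory time must be strictly positive (ti + hold < 60/rr)",
         call. = FALSE)
  }
  structure(as.list(vals), class = "ventilator_settings")
}

#' @export
print.ventilator_settings <- function(x, ...) {
  cat(sprintf(
    "<ventilator_settings> PEEP %.1f + dP %.1f cmH2O, RR %.1f /min, Ti %.2f s%s\n",
    x$peep, x$delta_p, x$rr, x$ti,
    if (x$hold_duration > 0) sprintf(", hold %.1f s", x$hold_duration) else ""))
  invisible(x)
}

# Zero-state inspiratory volume response (V0 = 0) at local times t, plus the
# homogeneous decay factor; covers the ideal square wave and a linear rise.
insp_response <- function(t, delta_p, crs, tau_i, rise_time) {
  veq <- delta_p * crs
  if (rise_time <= 0) {
    v <- veq * (1 - exp(-t / tau_i))
  } else {
    k <- delta_p / rise_time               # cmH2O/s
    v <- ifelse(t <= rise_time,
                k * crs * (t - tau_i * (1 - exp(-t / tau_i))),
                NA_real_)
    vr <- k * crs * (rise_time - tau_i * (1 - exp(-rise_time / tau_i)))
    post <- t > rise_time
    v[post] <- veq + (vr - veq) * exp(-(t[post] - rise_time) / tau_i)
  }
  v
}

# Closed-form cyclic steady state of the per-breath volume map.
steady_state_volumes <- function(mech, delta_p, ti_q, te_q, rise_time = 0) {
  tau_i <- mech$r_insp * mech$crs / 1000
  a <- exp(-ti_q / tau_i)
  b <- exp(-te_q / mech$rce)
  v_zero <- insp_response(ti_q, delta_p, mech$crs, tau_i, rise_time)
  v0 <- b * v_zero / (1 - a * b)   # fixed point of V0' = b*(v_zero + a*V0)
  v_ei <- v_zero + a * v0
  list(v0 = v0, v_ei = v_ei, tau_i = tau_i, a = a, b = b)
}

quantize <- function(x) max(1L, as.integer(round(x / WAVEFORM_DT)))

# Build the sample arrays for one breath starting at end-expiratory volume v0.
breath_samples <- function(mech, set, v0, hold = set$hold_duration) {
  tau_i <- mech$r_insp * mech$crs / 1000
  cycle <- 60 / set$rr
  n_ti <- quantize(set$ti)
  n_hold <- if (hold > 0) quantize(hold) else 0L
  n_te <- quantize(cycle - set$ti - set$hold_duration)
  t_i <- (seq_len(n_ti) - 1) * WAVEFORM_DT
  vol_i <- insp_response(t_i, set$delta_p, mech$crs, tau_i, set$rise_time) +
    v0 * exp(-t_i / tau_i)
  paw_i <- if (set$rise_time <= 0) {
    rep(set$peep + set$delta_p, n_ti)
  } else {
    set$peep + pmin(set$delta_p, set$delta_p * t_i / set$rise_time)
  }
  flow_i <- ((paw_i - set$peep) - vol_i / mech$crs) / (mech$r_insp / 1000)
  ti_q <- n_ti * WAVEFORM_DT
  v_ei <- insp_response(ti_q, set$delta_p, mech$crs, tau_i, set$rise_time) +
    v0 * exp(-ti_q / tau_i)
  plateau <- set$peep + v_ei / mech$crs
  if (n_hold > 0) {
    vol_h <- rep(v_ei, n_hold)
    paw_h <- rep(plateau, n_hold)
    flow_h <- rep(0, n_hold)
  } else {
    vol_h <- paw_h <- flow_h <- numeric(0)
  }
  t_e <- (seq_len(n_te) - 1) * WAVEFORM_DT
  vol_e <- v_ei * exp(-t_e / mech$rce)
  flow_e <- -(v_ei / mech$rce) * exp(-t_e / mech$rce)
  paw_e <- rep(set$peep, n_te)
  list(paw = c(paw_i, paw_h, paw_e),
       flow = c(flow_i, flow_h, flow_e),
       vol = c(vol_i, vol_h, vol_e) - v0,
       v_end = v_ei * exp(-n_te * WAVEFORM_DT / mech$rce),
       v_ei = v_ei, n = n_ti + n_hold + n_te,
       n_ti = n_ti, n_hold = n_hold)
}

new_breath_waveform <- function(time, paw, flow, volume, boundaries,
                                peep_set, auto_peep, peep_total) {
  structure(list(time = time, paw = paw, flow = flow, volume = volume,
                 breath_boundaries = boundaries),
            peep_set = peep_set, auto_peep = auto_peep,
            peep_total = peep_total, dt = WAVEFORM_DT,
            class = "breath_waveform")
}

#' @export
print.breath_waveform <- function(x, ...) {
  nb <- nrow(x$breath_boundaries)
  cat(sprintf("<breath_waveform> %d samples (%.1f s) in %d breath%s; auto-PEEP %.2f cmH2O\n",
              length(x$time), length(x$time) * attr(x, "dt"), nb,
              if (nb == 1) "" else "s", attr(x, "auto_peep")))
  invisible(x)
}

#' Simulate one pressure-controlled breath at cyclic steady state
#'
#' The breath is sampled on the ventilator's 0.01-s grid. Inspiratory and
#' expiratory phase durations are rounded to whole samples; the cyclic
#' steady state (geometric fixed point of the affine per-breath volume map)
#' is computed for the quantized durations, so trapped end-expiratory volume
#' and the resulting auto-PEEP are captured exactly whenever the expiratory
#' time is short relative to the expiratory time constant.
#'
#' @param mech a [patient_mechanics()] object.
#' @param set a [ventilator_settings()] object.
#' @return a `breath_waveform`: arrays `time` (s), `paw` (cmH2O), `flow`
#'   (ml/s, inspiration positive), `volume` (ml above the end-expiratory
#'   lung volume) and a `breath_boundaries` data frame of 1-based sample
#'   indices; attributes carry the set PEEP, auto-PEEP and total PEEP.
#' @export
simulate_breath <- function(mech, set) {
  stopifnot(inherits(mech, "patient_mechanics"),
            inherits(set, "ventilator_settings"))
  cycle <- 60 / set$rr
  ti_q <- quantize(set$ti) * WAVEFORM_DT
  te_q <- quantize(cycle - set$ti - set$hold_duration) * WAVEFORM_DT
  ss <- steady_state_volumes(mech, set$delta_p, ti_q, te_q, set$rise_time)
  b <- breath_samples(mech, set, ss$v0)
  bounds <- data.frame(breath = 1L, start = 1L, end = b$n)
  new_breath_waveform((seq_len(b$n) - 1) * WAVEFORM_DT,
                      b$paw, b$flow, b$vol, bounds,
                      peep_set = set$peep, auto_peep = ss$v0 / mech$crs,
                      peep_total = set$peep + ss$v0 / mech$crs)
}

#' Simulate a ventilation phase of repeated steady-state breaths
#'
#' Concatenates `n_breaths` identical steady-state breaths (the endpoints of
#' a one-hour phase are averaged over its final window, which at cyclic
#' steady state equals any window, so phases are simulated compressed).
#' Optionally appends a terminal end-inspiratory hold maneuver breath whose
#' cycle is extended by the occlusion, as when an operator triggers the
#' maneuver at the end of a phase.
#'
#' @inheritParams simulate_breath
#' @param n_breaths number of regular breaths (>= 1).
#' @param terminal_hold occlusion duration of an appended maneuver breath,
#'   s (2-3), or 0 for none.
#' @return a `breath_waveform` covering all breaths.
#' @export
simulate_phase <- function(mech, set, n_breaths, terminal_hold = 0) {
  stopifnot(inherits(mech, "patient_mechanics"),
            inherits(set, "ventilator_settings"))
  if (n_breaths < 1) stop("`n_breaths` must be >= 1", call. = FALSE)
  if (terminal_hold != 0 && (terminal_hold < 2 || terminal_hold > 3)) {
    stop("`terminal_hold` must be 0 or within 2-3 s", call. = FALSE)
  }
  cycle <- 60 / set$rr
  ti_q <- quantize(set$ti) * WAVEFORM_DT
  te_q <- quantize(cycle - set$ti - set$hold_duration) * WAVEFORM_DT
  ss <- steady_state_volumes(mech, set$delta_p, ti_q, te_q, set$rise_time)
  reg <- breath_samples(mech, set, ss$v0)
  nb <- as.integer(n_breaths)
  paw <- rep(reg$paw, nb); flow <- rep(reg$flow, nb); vol <- rep(reg$vol, nb)
  starts <- (seq_len(nb) - 1L) * reg$n + 1L
  ends <- seq_len(nb) * reg$n
  if (terminal_hold > 0) {
    man <- breath_samples(mech, set, ss$v0, hold = terminal_hold)
    paw <- c(paw, man$paw); flow <- c(flow, man$flow); vol <- c(vol, man$vol)
    starts <- c(starts, ends[nb] + 1L)
    ends <- c(ends, ends[nb] + man$n)
    nb <- nb + 1L
  }
  bounds <- data.frame(breath = seq_len(nb), start = starts, end = ends)
  new_breath_waveform((seq_along(paw) - 1) * WAVEFORM_DT, paw, flow, vol,
                      bounds, peep_set = set$peep,
                      auto_peep = ss$v0 / mech$crs,
                      peep_total = set$peep + ss$v0 / mech$crs)
}

#' Write / read the waveform CSV dialect
#'
#' One row per 0.01-s sample with header `time_s,paw_cmh2o,flow_ml_s,
#' volume_ml`, plus a companion CSV `breath_index,start_sample,end_sample`
#' (1-based sample indices) for the breath boundaries.
#'
#' @param wave a `breath_waveform`.
#' @param path CSV path for the samples.
#' @param boundaries_path CSV path for the breath boundaries.
#' @return `write_waveform_csv()` returns `path` invisibly;
#'   `read_waveform_csv()` returns a `breath_waveform`.
#' @export
write_waveform_csv <- function(wave, path, boundaries_path) {
  stopifnot(inherits(wave, "breath_waveform"))
  utils::write.csv(
    data.frame(time_s = wave$time, paw_cmh2o = wave$paw,
               flow_ml_s = wave$flow, volume_ml = wave$volume),
    path, row.names = FALSE)
  utils::write.csv(
    data.frame(breath_index = wave$breath_boundaries$breath,
               start_sample = wave$breath_boundaries$start,
               end_sample = wave$breath_boundaries$end),
    boundaries_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param peep_set set PEEP to attach to the imported waveform, cmH2O.
#' @export
read_waveform_csv <- function(path, boundaries_path, peep_set = NA_real_) {
  d <- utils::read.csv(path)
  need <- c("time_s", "paw_cmh2o", "flow_ml_s", "volume_ml")
  if (!all(need %in% names(d))) {
    stop("waveform CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (nrow(d) > 1) {
    dts <- diff(d$time_s)
    if (any(abs(dts - WAVEFORM_DT) > 1e-6)) {
      stop("waveform must be uniformly sampled at 0.01 s", call. = FALSE)
    }
  }
  bd <- utils::read.csv(boundaries_path)
  bounds <- data.frame(breath = bd$breath_index, start = bd$start_sample,
                       end = bd$end_sample)
  new_breath_waveform(d$time_s, d$paw_cmh2o, d$flow_ml_s, d$volume_ml,
                      bounds, peep_set = peep_set, auto_peep = NA_real_,
                      peep_total = NA_real_)
}
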