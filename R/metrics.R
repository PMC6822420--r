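# Waveform-derived lung-protection metrics.
#
# All integration is trapezoidal on the native 0.01-s grid, applied per
# breath phase (inspiration / occlusion / expiration, segmented by flow
# sign) because the idealized square-wave flow is discontinuous at phase
# transitions. Expired tidal volume is referenced to the breath's own
# end-expiratory volume.

FLOW_TOL <- 1e-6  # ml/s; below this a sample counts as zero flow

trapz <- function(y, dt = WAVEFORM_DT) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

# Segment one breath's samples into inspiration (positive flow), hold (zero
# flow after inspiration) and expiration (negative flow) runs.
segment_breath <- function(flow) {
  ph <- ifelse(flow > FLOW_TOL, 1L, ifelse(flow < -FLOW_TOL, -1L, 0L))
  r <- rle(ph)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(phase = r$values, start = starts, end = ends)
}

breath_slices <- function(wave) {
  bb <- wave$breath_boundaries
  lapply(seq_len(nrow(bb)), function(i) {
    idx <- bb$start[i]:bb$end[i]
    list(breath = bb$breath[i], idx = idx, time = wave$time[idx],
         paw = wave$paw[idx], flow = wave$flow[idx], vol = wave$volume[idx])
  })
}

# Locate an end-inspiratory occlusion (>= min_len s of zero flow preceded by
# inspiratory flow) inside one breath; NULL if absent.
find_hold <- function(sl, min_len = 2) {
  seg <- segment_breath(sl$flow)
  for (j in seq_len(nrow(seg))) {
    if (seg$phase[j] == 0L &&
        (seg$end[j] - seg$start[j] + 1L) * WAVEFORM_DT >= min_len &&
        j > 1 && seg$phase[j - 1L] == 1L) {
      return(seg$start[j]:seg$end[j])
    }
  }
  NULL
}

#' Static driving pressure from an end-inspiratory hold maneuver
#'
#' Scans the waveform for a breath containing an occlusion of at least 2 s
#' of zero flow after inspiration, reads the plateau pressure as the mean
#' airway pressure over the final 0.5 s of the hold and returns
#' `plateau - peep`. When the waveform carries an auto-PEEP attribute
#' (simulator output), the returned value exposes it as attribute
#' `auto_peep`: referencing the plateau to the set PEEP overstates the
#' purely elastic driving pressure by exactly that amount.
#'
#' @param wave a `breath_waveform` containing a hold maneuver.
#' @param peep set PEEP, cmH2O; defaults to the waveform's recorded value.
#' @return static driving pressure, cmH2O, with attributes `plateau` and
#'   (when known) `auto_peep`.
#' @export
driving_pressure_static <- function(wave, peep = attr(wave, "peep_set")) {
  stopifnot(inherits(wave, "breath_waveform"))
  if (!is.finite(peep)) stop("`peep` must be supplied", call. = FALSE)
  for (sl in rev(breath_slices(wave))) {   # prefer the terminal maneuver
    hold <- find_hold(sl)
    if (!is.null(hold)) {
      tail_n <- min(length(hold), as.integer(0.5 / WAVEFORM_DT))
      plateau <- mean(sl$paw[hold[(length(hold) - tail_n + 1L):length(hold)]])
      out <- plateau - peep
      attr(out, "plateau") <- plateau
      ap <- attr(wave, "auto_peep")
      if (!is.null(ap) && is.finite(ap)) attr(out, "auto_peep") <- ap
      return(out)
    }
  }
  stop("no inspiratory hold maneuver (>= 2 s of zero flow) found",
       call. = FALSE)
}

#' Static respiratory-system compliance
#'
#' @param vt_exp expired tidal volume, ml.
#' @param delta_p_stat static driving pressure, cmH2O (positive).
#' @return compliance in ml/cmH2O.
#' @export
static_compliance <- function(vt_exp, delta_p_stat) {
  if (!is.numeric(delta_p_stat) || any(delta_p_stat <= 0)) {
    stop("`delta_p_stat` must be positive", call. = FALSE)
  }
  vt_exp / delta_p_stat
}

#' Per-breath waveform metrics
#'
#' One row per complete breath: phase-segmented inspired and expired tidal
#' volumes, instantaneous rate, per-breath mean airway pressure, inspiratory
#' work (trapezoidal integral of absolute airway pressure over inspired
#' volume, in J), hold detection and, for hold breaths, plateau pressure.
#'
#' @param wave a `breath_waveform`.
#' @return a data frame of class `breath_metrics_stream`.
#' @export
breath_metrics <- function(wave) {
  stopifnot(inherits(wave, "breath_waveform"))
  rows <- lapply(breath_slices(wave), function(sl) {
    # tidal volumes from the integrated-volume channel (exact at the phase
    # transition, which a time-trapezoid of the discontinuous flow misses)
    peak <- which.max(sl$vol)
    vt_insp <- sl$vol[peak] - sl$vol[1]
    vt_exp <- sl$vol[peak] - sl$vol[length(sl$vol)]
    work <- if (peak > 1) {
      dv <- diff(sl$vol[1:peak])
      sum((sl$paw[1:(peak - 1)] + sl$paw[2:peak]) / 2 * dv) * CMH2O_ML_TO_J
    } else 0
    dur <- length(sl$idx) * WAVEFORM_DT
    hold <- find_hold(sl)
    plateau <- if (!is.null(hold)) {
      tail_n <- min(length(hold), as.integer(0.5 / WAVEFORM_DT))
      mean(sl$paw[hold[(length(hold) - tail_n + 1L):length(hold)]])
    } else NA_real_
    data.frame(breath = sl$breath,
               t_start = sl$time[1], t_end = sl$time[length(sl$time)],
               duration_s = dur, rr_inst = 60 / dur,
               vt_insp = vt_insp, vt_exp = vt_exp,
               paw_mean_breath = mean(sl$paw), work_j = work,
               has_hold = !is.null(hold), plateau = plateau)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("breath_metrics_stream", class(out))
  out
}

#' Total mechanical power delivered by the ventilator
#'
#' Per breath, the inspiratory pressure-volume integral (absolute airway
#' pressure, PEEP included) converted to Joules, averaged over regular
#' (non-maneuver) breaths and multiplied by the measured respiratory rate.
#'
#' @param wave a `breath_waveform` with at least one complete breath.
#' @return mechanical power, J/min.
#' @export
mechanical_power <- function(wave) {
  bm <- breath_metrics(wave)
  reg <- bm[!bm$has_hold, , drop = FALSE]
  if (nrow(reg) == 0) reg <- bm
  if (nrow(reg) == 0) stop("no complete breath in waveform", call. = FALSE)
  rr <- 60 / stats::median(reg$duration_s)
  mean(reg$work_j) * rr
}

#' Mean airway pressure over whole breath cycles
#'
#' @inheritParams mechanical_power
#' @return time-averaged airway pressure, cmH2O. Maneuver (hold) breaths are
#'   excluded so that a terminal occlusion does not bias the phase average.
#' @export
mean_airway_pressure <- function(wave) {
  stopifnot(inherits(wave, "breath_waveform"))
  if (length(wave$paw) == 0) stop("empty waveform", call. = FALSE)
  bm <- breath_metrics(wave)
  reg <- bm[!bm$has_hold, , drop = FALSE]
  if (nrow(reg) == 0) reg <- bm
  stats::weighted.mean(reg$paw_mean_breath, reg$duration_s)
}

#' Expiratory time constant from the passive expiratory limb
#'
#' Least-squares fit of expiratory volume against flow (slope with
#' intercept) over the central 75\% to 25\% expired-volume window of the
#' last complete breath. For a linear single-compartment expiration
#' `flow = -(V + V_trapped)/tau`, so the slope recovers `tau` exactly even
#' when expiration is truncated; a truncation flag (attribute `truncated`)
#' is set when end-expiratory flow still exceeds 5\% of peak expiratory
#' flow.
#'
#' @inheritParams mechanical_power
#' @return estimated time constant, s.
#' @export
expiratory_time_constant <- function(wave) {
  stopifnot(inherits(wave, "breath_waveform"))
  for (sl in rev(breath_slices(wave))) {
    seg <- segment_breath(sl$flow)
    expn <- seg[seg$phase == -1L, , drop = FALSE]
    if (nrow(expn) == 0) next
    j <- which.max(expn$end - expn$start)
    i <- expn$start[j]:expn$end[j]
    v <- sl$vol[i]; f <- sl$flow[i]
    rng <- v[1] - v[length(v)]
    if (length(i) < 5 || rng <= 0) next
    frac <- (v - v[length(v)]) / rng
    w <- which(frac <= 0.75 & frac >= 0.25)
    if (length(w) < 3) {
      stop("expiration too short for the 75-25% fit window", call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(1, f[w]), v[w])
    tau <- -fit$coefficients[[2]]
    if (!is.finite(tau) || tau <= 0) {
      stop("expiratory fit did not yield a positive time constant",
           call. = FALSE)
    }
    attr(tau, "truncated") <- abs(f[length(f)]) > 0.05 * max(abs(f))
    return(tau)
  }
  stop("no passive expiration found in waveform", call. = FALSE)
}

#' Bohr dead space from arterial and expired CO2 tensions
#'
#' `VD = VT * (PaCO2 - PeCO2) / PaCO2`. Supplying the end-tidal tension
#' gives the end-tidal (Enghoff-style) estimate; supplying a mixed-expired
#' tension (see [mixed_expired_co2()]) gives the physiological dead space.
#'
#' @param paco2 arterial CO2 tension, mmHg (positive).
#' @param eco2 expired CO2 tension, mmHg, in `[0, paco2]`.
#' @param vt tidal volume, ml.
#' @return dead space, ml.
#' @export
#' @examples
#' bohr_dead_space(40, 30, 500) # 125 ml
bohr_dead_space <- function(paco2, eco2, vt) {
  if (any(paco2 <= 0)) stop("`paco2` must be positive", call. = FALSE)
  if (any(eco2 < 0) || any(eco2 > paco2)) {
    stop("`eco2` must lie within [0, paco2]", call. = FALSE)
  }
  vt * (paco2 - eco2) / paco2
}

#' Alveolar minute ventilation
#'
#' Dead space is subtracted from the tidal volume and the alveolar tidal
#' volume multiplied by the respiratory rate.
#'
#' @param vt tidal volume, ml.
#' @param vd dead space, ml, in `[0, vt]`.
#' @param rr respiratory rate, breaths/min.
#' @return alveolar minute ventilation, ml/min.
#' @export
alveolar_minute_ventilation <- function(vt, vd, rr) {
  if (any(vd < 0) || any(vd > vt)) {
    stop("`vd` must lie within [0, vt]", call. = FALSE)
  }
  (vt - vd) * rr
}

#' Average per-breath metrics over the final window of a phase
#'
#' Arithmetic mean of each numeric per-breath field over the complete
#' breaths whose end falls inside the final `window` seconds (the study
#' endpoints are averaged over the last 5 min of each phase).
#'
#' @param metrics a [breath_metrics()] data frame.
#' @param window averaging window, s (default 300).
#' @return a one-row data frame of window means (fields only defined on
#'   hold breaths, such as the plateau, are averaged over those breaths).
#' @export
window_average <- function(metrics, window = 300) {
  stopifnot(inherits(metrics, "breath_metrics_stream") ||
              is.data.frame(metrics))
  span <- max(metrics$t_end) - min(metrics$t_start)
  if (span < window) {
    stop(sprintf("stream spans %.1f s, shorter than the %.1f s window",
                 span, window), call. = FALSE)
  }
  keep <- metrics[metrics$t_end > max(metrics$t_end) - window, , drop = FALSE]
  num <- vapply(keep, is.numeric, logical(1))
  out <- as.data.frame(lapply(keep[num], mean, na.rm = TRUE))
  out$n_breaths <- nrow(keep)
  out
}

#' @rdname breath_metrics
#' @param metrics a [breath_metrics()] data frame.
#' @param path output CSV path.
#' @export
write_breath_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
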