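# Steady-state CO2 gas exchange.

#' Steady-state arterial and end-tidal CO2 for a given alveolar ventilation
#'
#' Alveolar ventilation equation: `PaCO2 = 0.863 * VCO2 / VA` with `VCO2` in
#' ml/min (STPD) and `VA` in l/min (BTPS). The end-tidal value is the
#' arterial value minus the patient's arterial-to-end-tidal gradient,
#' floored at zero.
#'
#' @param mech a [patient_mechanics()] object (supplies `vco2` and
#'   `etco2_gradient`).
#' @param va alveolar minute ventilation, ml/min (positive).
#' @return an object of class `gas_state`: `paco2`, `etco2` (mmHg) and `va`
#'   (ml/min).
#' @export
#' @examples
#' m <- patient_mechanics(crs = 55, r_insp = 11, rce = 0.82, pbw = 74,
#'                        vco2 = 200, etco2_gradient = 0)
#' gas_exchange_steady_state(m, 4315)  # PaCO2 = etCO2 = 40 mmHg
gas_exchange_steady_state <- function(mech, va) {
  stopifnot(inherits(mech, "patient_mechanics"))
  if (!is.numeric(va) || !is.finite(va) || va <= 0) {
    stop("`va` must be a positive alveolar ventilation in ml/min",
         call. = FALSE)
  }
  paco2 <- 0.863 * mech$vco2 / (va / 1000)
  etco2 <- max(paco2 - mech$etco2_gradient, 0)
  structure(list(paco2 = paco2, etco2 = etco2, va = va),
            class = "gas_state")
}

#' @export
print.gas_state <- function(x, ...) {
  cat(sprintf("<gas_state> PaCO2 %.1f, etCO2 %.1f mmHg at VA %.2f l/min\n",
              x$paco2, x$etco2, x$va / 1000))
  invisible(x)
}

#' Mixed-expired CO2 tension implied by the patient's dead space
#'
#' The expired breath dilutes alveolar gas with the CO2-free physiological
#' dead space (anatomical series dead space plus the alveolar dead-space
#' fraction of the alveolar tidal volume), so
#' `PeCO2 = PaCO2 * (1 - VDphys/VT)`. Feeding this tension to
#' [bohr_dead_space()] recovers the physiological dead space, as volumetric
#' capnography would.
#'
#' @inheritParams gas_exchange_steady_state
#' @param paco2 arterial CO2 tension, mmHg.
#' @param vt tidal volume, ml (must exceed the anatomical dead space).
#' @return mixed-expired CO2 tension, mmHg.
#' @export
mixed_expired_co2 <- function(mech, paco2, vt) {
  stopifnot(inherits(mech, "patient_mechanics"))
  if (vt <= mech$vda) {
    stop("`vt` must exceed the anatomical dead space", call. = FALSE)
  }
  vd_phys <- mech$vda + mech$dead_space_fraction * (vt - mech$vda)
  paco2 * (1 - vd_phys / vt)
}

# True alveolar minute ventilation of the model (ml/min): tidal volume minus
# physiological dead space, times rate.
model_alveolar_ventilation <- function(mech, vt, rr) {
  (1 - mech$dead_space_fraction) * (vt - mech$vda) * rr
}
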