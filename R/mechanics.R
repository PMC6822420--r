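# Respiratory-mechanics parameter objects and derived quantities.

# 1 cmH2O * 1 ml = 9.80665e-5 J (exact, by definition of cmH2O)
CMH2O_ML_TO_J <- 9.80665e-5

#' Anatomical (series) dead space from predicted body weight
#'
#' The airway dead space is assumed proportional to predicted body weight at
#' 2.2 ml/kg, the convention used by adaptive ventilation modes when no
#' measured value is available.
#'
#' @param pbw predicted body weight in kg (positive).
#' @return anatomical dead space in ml.
#' @export
#' @examples
#' anatomical_dead_space(74) # 162.8 ml
anatomical_dead_space <- function(pbw) {
  if (!is.numeric(pbw) || any(!is.finite(pbw)) || any(pbw <= 0)) {
    stop("`pbw` must be a positive, finite body weight in kg", call. = FALSE)
  }
  2.2 * pbw
}

#' Predicted body weight from height and sex
#'
#' Standard ARDSNet formula: 50 kg (male) or 45.5 kg (female) plus
#' 0.905 kg per cm above 152.4 cm.
#'
#' @param height_cm body height in cm, within 120-220.
#' @param sex `"male"` or `"female"`.
#' @return predicted body weight in kg.
#' @export
predicted_body_weight <- function(height_cm, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (!is.numeric(height_cm) || any(!is.finite(height_cm)) ||
      any(height_cm < 120) || any(height_cm > 220)) {
    stop("`height_cm` must lie within 120-220 cm", call. = FALSE)
  }
  base <- if (sex == "male") 50 else 45.5
  base + 0.905 * (height_cm - 152.4)
}

#' Respiratory-system mechanics of a (simulated) patient
#'
#' Bundles the linear single-compartment parameters: static compliance,
#' separate inspiratory and expiratory resistances, anatomical dead space,
#' CO2 production and the gas-exchange measurement constants. Exactly one of
#' `r_exp` or `rce` must be given; the other is derived from
#' `rce = r_exp * crs / 1000` (resistance in cmH2O.s/l, compliance in
#' ml/cmH2O, time constant in s).
#'
#' @param crs static respiratory-system compliance, ml/cmH2O.
#' @param r_insp inspiratory resistance, cmH2O.s/l.
#' @param r_exp expiratory resistance, cmH2O.s/l (or `NULL` if `rce` given).
#' @param rce expiratory time constant, s (or `NULL` if `r_exp` given).
#' @param pbw predicted body weight, kg.
#' @param vda anatomical dead space, ml; defaults to 2.2 ml/kg PBW.
#' @param vco2 CO2 production, ml/min.
#' @param etco2_gradient arterial minus end-tidal CO2 difference, mmHg.
#' @param dead_space_fraction alveolar dead-space fraction of alveolar tidal
#'   volume (dimensionless, in `[0, 0.6)`); together with `vda` it forms the
#'   physiological dead space seen by gas exchange.
#' @return an object of class `patient_mechanics`.
#' @export
patient_mechanics <- function(crs, r_insp, r_exp = NULL, rce = NULL,
                              pbw, vda = anatomical_dead_space(pbw),
                              vco2 = 200, etco2_gradient = 4,
                              dead_space_fraction = 0.15) {
  if (is.null(r_exp) && is.null(rce)) {
    stop("supply one of `r_exp` or `rce`", call. = FALSE)
  }
  if (is.null(r_exp)) r_exp <- rce * 1000 / crs
  if (is.null(rce))   rce <- r_exp * crs / 1000
  m <- structure(
    list(crs = crs, r_insp = r_insp, r_exp = r_exp, rce = rce,
         pbw = pbw, vda = vda, vco2 = vco2,
         etco2_gradient = etco2_gradient,
         dead_space_fraction = dead_space_fraction),
    class = "patient_mechanics")
  validate_patient_mechanics(m)
}

validate_patient_mechanics <- function(m) {
  num <- vapply(m, function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num)) stop("all mechanics fields must be finite scalars",
                      call. = FALSE)
  pos <- c("crs", "r_insp", "r_exp", "pbw", "vda", "vco2")
  for (f in pos) if (m[[f]] <= 0) {
    stop(sprintf("`%s` must be positive", f), call. = FALSE)
  }
  if (m$etco2_gradient < 0) {
    stop("`etco2_gradient` must be non-negative", call. = FALSE)
  }
  if (m$dead_space_fraction < 0 || m$dead_space_fraction >= 0.6) {
    stop("`dead_space_fraction` must lie in [0, 0.6)", call. = FALSE)
  }
  if (abs(m$rce - m$r_exp * m$crs / 1000) > 1e-9) {
    stop("`rce` inconsistent with `r_exp * crs / 1000`", call. = FALSE)
  }
  m
}

#' @export
print.patient_mechanics <- function(x, ...) {
  cat("<patient_mechanics>\n")
  cat(sprintf("  Crs %.1f ml/cmH2O | Rinsp %.1f, Rexp %.1f cmH2O.s/l | RCe %.2f s\n",
              x$crs, x$r_insp, x$r_exp, x$rce))
  cat(sprintf("  PBW %.1f kg | VDa %.1f ml | VCO2 %.0f ml/min | Pa-etCO2 %.1f mmHg\n",
              x$pbw, x$vda, x$vco2, x$etco2_gradient))
  invisible(x)
}

#' Is a patient eligible for the cross-over protocol?
#'
#' Patients with an expiratory time constant above 1.5 s (significant
#' expiratory flow limitation) are excluded.
#'
#' @param mech a [patient_mechanics()] object.
#' @return logical scalar.
#' @export
trial_eligible <- function(mech) {
  stopifnot(inherits(mech, "patient_mechanics"))
  mech$rce <= 1.5
}
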