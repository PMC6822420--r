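# Synthetic virtual-patient cohort calibrated to a critically-ill ICU
# population on controlled ventilation (with an ARDS subgroup of lower
# compliance).
#
# Marginals are truncated normals; compliance and the expiratory time
# constant are coupled through a Gaussian copula because the delivered
# tidal volume of the power-minimizing mode is observed to track compliance
# tightly, which bounds that coupling from below. CO2 production is derived
# so that the baseline ventilation and the sampled arterial CO2 are
# mutually consistent under the steady-state gas model.

#' Cohort distribution parameters
#'
#' Each continuous parameter is given as `c(mean, sd, lower, upper)` for a
#' truncated-normal draw; PEEP is a discrete distribution on whole cmH2O
#' values with median 8 and interquartile range 8-10.
#'
#' @param crs,crs_ards compliance, ml/cmH2O (general / ARDS subgroup).
#' @param rce,rce_ards expiratory time constant, s; the upper truncation at
#'   1.5 s enforces trial eligibility.
#' @param r_insp inspiratory resistance, cmH2O.s/l.
#' @param pbw predicted body weight, kg.
#' @param vt_kg baseline tidal volume, ml/kg PBW.
#' @param rr baseline respiratory rate, breaths/min.
#' @param paco2 baseline arterial CO2, mmHg.
#' @param etco2_gradient arterial-to-end-tidal CO2 difference, mmHg.
#' @param dead_space_fraction alveolar dead-space fraction.
#' @param peep_values,peep_probs discrete PEEP distribution, cmH2O.
#' @param crs_rce_correlation Gaussian-copula correlation between
#'   compliance and the expiratory time constant.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(crs = c(55, 13, 20, 100),
                          crs_ards = c(47, 9, 20, 100),
                          rce = c(0.82, 0.22, 0.3, 1.5),
                          rce_ards = c(0.73, 0.18, 0.3, 1.5),
                          r_insp = c(11.1, 2.3, 4, 25),
                          pbw = c(74, 10, 45, 110),
                          vt_kg = c(7.5, 0.8, 5, 10),
                          rr = c(15.3, 1.8, 10, 25),
                          paco2 = c(43, 6, 30, 70),
                          etco2_gradient = c(4, 2, 0.5, 10),
                          dead_space_fraction = c(0.15, 0.07, 0, 0.35),
                          peep_values = 5:14,
                          peep_probs = c(0.04, 0.08, 0.10, 0.36, 0.11,
                                         0.16, 0.05, 0.05, 0.03, 0.02),
                          crs_rce_correlation = 0.85) {
  p <- structure(
    list(crs = crs, crs_ards = crs_ards, rce = rce, rce_ards = rce_ards,
         r_insp = r_insp, pbw = pbw, vt_kg = vt_kg, rr = rr, paco2 = paco2,
         etco2_gradient = etco2_gradient,
         dead_space_fraction = dead_space_fraction,
         peep_values = peep_values, peep_probs = peep_probs / sum(peep_probs),
         crs_rce_correlation = crs_rce_correlation),
    class = "cohort_params")
  cont <- setdiff(names(p), c("peep_values", "peep_probs",
                              "crs_rce_correlation"))
  for (f in cont) {
    v <- p[[f]]
    if (length(v) != 4 || v[2] < 0 || v[3] >= v[4]) {
      stop(sprintf("`%s` must be c(mean, sd >= 0, lower < upper)", f),
           call. = FALSE)
    }
  }
  if (p$rce[4] > 1.5 || p$rce_ards[4] > 1.5) {
    stop("`rce` truncation must respect the 1.5-s eligibility bound",
         call. = FALSE)
  }
  if (abs(p$crs_rce_correlation) >= 1) {
    stop("`crs_rce_correlation` must lie in (-1, 1)", call. = FALSE)
  }
  p
}

rtruncnorm1 <- function(spec) {
  for (k in 1:1000) {
    x <- stats::rnorm(1, spec[1], spec[2])
    if (x >= spec[3] && x <= spec[4]) return(x)
  }
  stop("infeasible parameters: truncation bounds cannot be satisfied",
       call. = FALSE)
}

#' Draw one synthetic patient
#'
#' Rejection-samples truncated-normal mechanics (the ARDS subgroup uses its
#' own compliance and time-constant distributions), derives the expiratory
#' resistance from `rce` and `crs`, and sets the CO2 production so that the
#' baseline alveolar ventilation reproduces the sampled arterial CO2.
#'
#' @param rng_seed integer seed (the draw is a pure function of it).
#' @param params a [cohort_params()].
#' @param ards logical: use the ARDS parameter set.
#' @param id patient label.
#' @return an object of class `synthetic_patient`: fields `id`, `ards`,
#'   `mech` ([patient_mechanics()]) and `baseline` (settings and gas state).
#' @export
sample_patient <- function(rng_seed, params = cohort_params(), ards = FALSE,
                           id = sprintf("P%04d", rng_seed %% 10000L)) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(rng_seed)
  crs_spec <- if (ards) params$crs_ards else params$crs
  rce_spec <- if (ards) params$rce_ards else params$rce
  rho <- params$crs_rce_correlation
  for (k in 1:1000) {
    z1 <- stats::rnorm(1)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
    crs <- crs_spec[1] + crs_spec[2] * z1
    rce <- rce_spec[1] + rce_spec[2] * z2
    if (crs >= crs_spec[3] && crs <= crs_spec[4] &&
        rce >= rce_spec[3] && rce <= rce_spec[4]) break
    if (k == 1000) {
      stop("infeasible parameters: could not draw eligible mechanics",
           call. = FALSE)
    }
  }
  pbw <- rtruncnorm1(params$pbw)
  r_insp <- rtruncnorm1(params$r_insp)
  vt_kg <- rtruncnorm1(params$vt_kg)
  rr_b <- rtruncnorm1(params$rr)
  paco2 <- rtruncnorm1(params$paco2)
  grad <- rtruncnorm1(params$etco2_gradient)
  fa <- rtruncnorm1(params$dead_space_fraction)
  peep <- sample(params$peep_values, 1, prob = params$peep_probs)
  vda <- anatomical_dead_space(pbw)
  vt_b <- vt_kg * pbw
  va_b <- (1 - fa) * (vt_b - vda) * rr_b         # ml/min
  vco2 <- paco2 * (va_b / 1000) / 0.863
  mech <- patient_mechanics(crs = crs, r_insp = r_insp, rce = rce,
                            pbw = pbw, vda = vda, vco2 = vco2,
                            etco2_gradient = grad,
                            dead_space_fraction = fa)
  gas <- gas_exchange_steady_state(mech, va_b)
  structure(list(id = id, ards = ards, mech = mech,
                 baseline = list(vt_kg = vt_kg, vt = vt_b, rr = rr_b,
                                 ve = vt_b * rr_b, va = va_b, peep = peep,
                                 paco2 = gas$paco2, etco2 = gas$etco2)),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> %s%s Crs %.1f, RCe %.2f s, PBW %.1f kg, PEEP %d\n",
              x$id, if (x$ards) " [ARDS]" else "", x$mech$crs, x$mech$rce,
              x$mech$pbw, as.integer(x$baseline$peep)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Per-patient seeds are derived deterministically from the master seed, so
#' a cohort is a pure function of `(n, ards_n, seed, params)`.
#'
#' @param n cohort size (>= 1).
#' @param ards_n number of ARDS patients (0..n).
#' @param seed master integer seed.
#' @param params a [cohort_params()].
#' @return an object of class `synthetic_cohort` (list of
#'   [sample_patient()] results).
#' @export
#' @examples
#' cohort <- generate_cohort(4, 2, seed = 1)
generate_cohort <- function(n, ards_n, seed, params = cohort_params()) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (ards_n < 0 || ards_n > n) {
    stop("`ards_n` must lie within [0, n]", call. = FALSE)
  }
  set.seed(seed)
  pat_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ards <- rep(c(TRUE, FALSE), c(ards_n, n - ards_n))
  pats <- lapply(seq_len(n), function(i) {
    sample_patient(pat_seeds[i], params, ards[i], id = sprintf("P%02d", i))
  })
  structure(pats, class = "synthetic_cohort", seed = seed)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<synthetic_cohort> %d patients (%d ARDS)\n",
              nrow(df), sum(df$ards)))
  cat(sprintf("  Crs %.1f +/- %.1f ml/cmH2O | RCe %.2f +/- %.2f s | PBW %.0f +/- %.0f kg\n",
              mean(df$crs), stats::sd(df$crs), mean(df$rce),
              stats::sd(df$rce), mean(df$pbw), stats::sd(df$pbw)))
  invisible(x)
}

#' @export
as.data.frame.synthetic_cohort <- function(x, ...) {
  do.call(rbind, lapply(x, function(p) {
    data.frame(id = p$id, ards = p$ards, crs = p$mech$crs,
               r_insp = p$mech$r_insp, r_exp = p$mech$r_exp,
               rce = p$mech$rce, pbw = p$mech$pbw, vda = p$mech$vda,
               vco2 = p$mech$vco2, etco2_gradient = p$mech$etco2_gradient,
               dead_space_fraction = p$mech$dead_space_fraction,
               baseline_vt_kg = p$baseline$vt_kg,
               baseline_rr = p$baseline$rr, baseline_ve = p$baseline$ve,
               baseline_paco2 = p$baseline$paco2,
               baseline_etco2 = p$baseline$etco2, peep = p$baseline$peep)
  }))
}

#' @rdname generate_cohort
#' @param cohort a `synthetic_cohort`.
#' @param path output CSV path (one row per patient).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
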