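# Respiratory-rate selection for adaptive ventilation.
#
# Both adaptive modes pick the RR that delivers a target expiratory minute
# ventilation VE given the anatomical dead space VDa and the expiratory time
# constant RCe:
#
#   AVM  (Otis):      RR = [sqrt(1 + 4 pi^2 RCe (VE - VDa RR)/VDa) - 1] /
#                          (2 pi^2 RCe)
#   AVM2 (min power): RR = VE/(2 VDa) * (1 - 1/(2 RR RCe (e^(1/(2 RR RCe)) - 1)))
#
# evaluated in coherent units (RR breaths/s, VE ml/s, VDa ml, RCe s) and
# solved by damped fixed-point iteration. The AVM2 form is the stationarity
# condition of the square-wave inspiratory-power objective at fixed alveolar
# ventilation (see power_curve() for the brute-force check).

#' Input set for respiratory-rate selection
#'
#' @param ve target expiratory minute ventilation, ml/min.
#' @param vda anatomical dead space, ml.
#' @param rce expiratory time constant, s (non-negative).
#' @param rr_min,rr_max solver bounds in breaths/min.
#' @return an object of class `rr_selection_input`.
#' @export
#' @examples
#' rr_selection_input(ve = 8491, vda = 162.8, rce = 0.82)
rr_selection_input <- function(ve, vda, rce, rr_min = 4, rr_max = 60) {
  stopifnot(is.numeric(ve), is.numeric(vda), is.numeric(rce))
  if (ve <= 0) stop("`ve` must be positive (ml/min)", call. = FALSE)
  if (vda <= 0) stop("`vda` must be positive (ml)", call. = FALSE)
  if (rce < 0) stop("`rce` must be non-negative (s)", call. = FALSE)
  if (!(rr_min > 0 && rr_min < rr_max)) {
    stop("need 0 < rr_min < rr_max", call. = FALSE)
  }
  structure(list(ve = ve, vda = vda, rce = rce,
                 rr_min = rr_min, rr_max = rr_max),
            class = "rr_selection_input")
}

# Iteration maps in canonical units (breaths/s, ml/s). The Otis map uses the
# rearrangement sqrt(1+e)-1 = e/(sqrt(1+e)+1) which is exact and keeps full
# precision as RCe -> 0; both maps reduce to VE/(2 VDa) in that limit.
otis_map <- function(rr, ve, vda, rce) {
  eps <- 4 * pi^2 * rce * (ve - vda * rr) / vda
  if (eps < -1) return(NA_real_)
  (eps / (sqrt(1 + eps) + 1)) / (2 * pi^2 * rce)
}

minpower_map <- function(rr, ve, vda, rce) {
  x <- 2 * rr * rce
  if (x <= 0) return(NA_real_)
  ve / (2 * vda) * (1 - 1 / (x * expm1(1 / x)))
}

# Damped fixed-point solver with bracketed root fallback; everything in
# canonical breaths/s. Plain iteration of the min-power map oscillates, a
# damping factor of 0.5 makes both maps contract over the admissible range.
solve_rr_fixed_point <- function(map, inp, lambda = 0.5, tol = 1e-11,
                                 max_iter = 500L) {
  ve_s <- inp$ve / 60
  lim <- ve_s / (2 * inp$vda)      # shared RCe -> 0 limit, breaths/s
  if (inp$rce < 1e-12) {
    return(list(rr_s = lim, residual = 0, iterations = 0L))
  }
  f <- function(rr) map(rr, ve_s, inp$vda, inp$rce)
  x <- 15 / 60
  hi <- ve_s / inp$vda             # admissibility: VE - VDa*RR > 0
  for (k in seq_len(max_iter)) {
    fx <- f(x)
    if (!is.finite(fx)) break
    xn <- (1 - lambda) * x + lambda * fx
    xn <- min(max(xn, 1e-9), hi * (1 - 1e-12))
    if (abs(xn - x) < tol) {
      return(list(rr_s = xn, residual = abs(xn - f(xn)), iterations = k))
    }
    x <- xn
  }
  # fallback: bracketed root of g(rr) = rr - f(rr) over the solver bounds
  g <- function(rr) rr - f(rr)
  lo <- inp$rr_min / 60
  up <- min(inp$rr_max / 60, hi * (1 - 1e-9))
  glo <- g(lo); gup <- g(up)
  if (!is.finite(glo) || !is.finite(gup) || glo * gup > 0) {
    stop("no admissible fixed point with positive alveolar ventilation",
         call. = FALSE)
  }
  r <- stats::uniroot(g, c(lo, up), tol = 1e-12)
  list(rr_s = r$root, residual = abs(g(r$root)), iterations = max_iter)
}

rr_selection_result <- function(sol, inp, mode) {
  rr <- sol$rr_s * 60
  if (inp$ve - inp$vda * rr <= 0) {
    stop("no admissible solution: alveolar ventilation not positive",
         call. = FALSE)
  }
  clamped <- rr < inp$rr_min || rr > inp$rr_max
  rr_out <- min(max(rr, inp$rr_min), inp$rr_max)
  structure(list(rr = rr_out, rr_unclamped = rr, clamped = clamped,
                 vt = inp$ve / rr, residual = sol$residual,
                 iterations = sol$iterations, mode = mode,
                 input = inp),
            class = "rr_selection")
}

#' @export
print.rr_selection <- function(x, ...) {
  cat(sprintf("<rr_selection> %s: RR %.2f /min, VT %.1f ml%s\n",
              x$mode, x$rr, x$vt, if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Select the respiratory rate by Otis' least-work-of-breathing equation (AVM)
#'
#' Solves the modified Otis equation for its fixed point by damped iteration
#' (step 0.5, start 15/min, residual below 1e-9 breaths/s), with a bracketed
#' root-finding fallback. The returned rate is reported in breaths/min and
#' clamped (with `clamped = TRUE`) if it falls outside the solver bounds.
#'
#' @param inp an [rr_selection_input()].
#' @return an `rr_selection` object: fields `rr` (breaths/min), `vt`
#'   (delivered tidal volume at the target ventilation, ml), `clamped`,
#'   `residual` (breaths/s) and `iterations`.
#' @seealso [select_rr_minpower()], [power_curve()]
#' @export
#' @examples
#' select_rr_otis(rr_selection_input(8491, 162.8, 0.82)) # about 13.6 /min
select_rr_otis <- function(inp) {
  stopifnot(inherits(inp, "rr_selection_input"))
  rr_selection_result(solve_rr_fixed_point(otis_map, inp), inp, "AVM")
}

#' Select the respiratory rate by minimization of inspiratory power (AVM2)
#'
#' Solves the fixed point of the inspiratory-power stationarity condition.
#' Because the bracketed correction factor lies strictly inside (0, 1), the
#' selected rate is always below `VE/(2 VDa)` and the delivered tidal volume
#' always exceeds twice the anatomical dead space.
#'
#' @inheritParams select_rr_otis
#' @return an `rr_selection` object, see [select_rr_otis()].
#' @export
#' @examples
#' select_rr_minpower(rr_selection_input(8491, 162.8, 0.82)) # about 18.1 /min
select_rr_minpower <- function(inp) {
  stopifnot(inherits(inp, "rr_selection_input"))
  rr_selection_result(solve_rr_fixed_point(minpower_map, inp), inp, "AVM2")
}

#' Inspiratory power of an ideal square-wave breath
#'
#' Work per breath is the pressure difference above PEEP times the tidal
#' volume (the area of the idealized pressure-volume loop); multiplying by
#' the rate gives power in J/min.
#'
#' @param rr respiratory rate, breaths/min.
#' @param delta_p inspiratory pressure above PEEP, cmH2O.
#' @param vt tidal volume, ml.
#' @return inspiratory power, J/min.
#' @export
#' @examples
#' inspiratory_power_square_wave(10, 10, 500) # 4.903 J/min
inspiratory_power_square_wave <- function(rr, delta_p, vt) {
  if (any(!is.finite(c(rr, delta_p, vt))) || any(c(rr, delta_p, vt) < 0)) {
    stop("`rr`, `delta_p` and `vt` must be non-negative", call. = FALSE)
  }
  rr * delta_p * vt * CMH2O_ML_TO_J
}

#' Brute-force inspiratory-power curve over a respiratory-rate grid
#'
#' Independent verification oracle for [select_rr_minpower()]. Alveolar
#' ventilation is held fixed at the value implied by the candidate fixed
#' point; for each rate on the grid the tidal volume, the square-wave
#' driving pressure needed to deliver it in the available inspiratory time
#' (finite-time exponential inflation with time constant `rce`), and the
#' resulting inspiratory power are evaluated. The argmin of this curve must
#' coincide with the fixed point of the selection equation.
#'
#' @param inp an [rr_selection_input()].
#' @param crs respiratory-system compliance, ml/cmH2O.
#' @param ie_inspiratory_fraction fraction of the breath cycle spent in
#'   inspiration (default 0.5, i.e. I:E = 1:1).
#' @param resolution grid step in breaths/min.
#' @return an object of class `power_curve` with fields `rr_grid`
#'   (breaths/min), `power` (J/min), `argmin_rr` and `boundary` (flag set
#'   when the minimum sits on the grid edge).
#' @export
power_curve <- function(inp, crs, ie_inspiratory_fraction = 0.5,
                        resolution = 0.01) {
  stopifnot(inherits(inp, "rr_selection_input"))
  if (!(crs > 0)) stop("`crs` must be positive", call. = FALSE)
  if (ie_inspiratory_fraction <= 0 || ie_inspiratory_fraction >= 1) {
    stop("`ie_inspiratory_fraction` must lie in (0, 1)", call. = FALSE)
  }
  cand <- select_rr_minpower(inp)
  va_star <- inp$ve - inp$vda * cand$rr_unclamped   # ml/min, held fixed
  rr <- seq(inp$rr_min, inp$rr_max, by = resolution)
  vt <- va_star / rr + inp$vda
  ti <- ie_inspiratory_fraction * 60 / rr
  infl <- if (inp$rce < 1e-12) rep(1, length(ti)) else -expm1(-ti / inp$rce)
  delta_p <- vt / (crs * infl)
  power <- rr * delta_p * vt * CMH2O_ML_TO_J
  i <- which.min(power)
  structure(list(rr_grid = rr, power = power, argmin_rr = rr[i],
                 boundary = i == 1L || i == length(rr),
                 candidate_rr = cand$rr_unclamped),
            class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("<power_curve> %d points, argmin %.2f /min (%.3f J/min)%s\n",
              length(x$rr_grid), x$argmin_rr, min(x$power),
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}
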