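# Paired cross-over statistics: normality-driven test selection, the
# D'Agostino-Pearson omnibus normality test, Pearson correlation and the
# noncentral-t paired sample-size calculation.

#' D'Agostino-Pearson omnibus K2 normality test
#'
#' Combines the null-transformed sample skewness (D'Agostino's Z of
#' sqrt(b1)) and kurtosis (Anscombe-Glynn's Z of b2) into
#' `K2 = Z(skew)^2 + Z(kurt)^2`, referred to a chi-square distribution with
#' 2 degrees of freedom.
#'
#' @param x numeric vector, length >= 8.
#' @return a list with `k2`, `p_value`, `z_skew`, `z_kurt` and `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson K2 requires n >= 8", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("zero variance: normality test undefined", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  num <- (1 - 2 / a) / (1 + xs * sqrt(2 / (a - 4)))
  z_kurt <- ((1 - 2 / (9 * a)) - sign(num) * abs(num)^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  list(k2 = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Paired two-mode comparison with normality-driven test selection
#'
#' Differences are tested for normality with [dagostino_pearson()] (which
#' needs at least 8 pairs; fewer fall back to the rank test). Normal-looking
#' differences (K2 p >= 0.05) get the paired two-sided t test; otherwise the
#' Wilcoxon matched-pairs signed-rank test is used, exact for up to 25
#' non-zero differences and with continuity-corrected normal approximation
#' above, zero differences dropped.
#'
#' @param x,y paired per-patient values (equal length >= 3).
#' @param label endpoint label carried into the result.
#' @param test `"auto"` applies the normality decision rule; `"paired_t"`
#'   or `"wilcoxon"` force a branch.
#' @return an object of class `paired_test_result`: `label`, `test`
#'   (`"paired_t"`, `"wilcoxon"` or `"degenerate"`), `statistic`,
#'   `p_value`, `estimate` (mean difference for t, median difference for
#'   Wilcoxon), `dispersion` (SD or IQR of the differences) and `n`.
#' @export
paired_compare <- function(x, y, label = "endpoint",
                           test = c("auto", "paired_t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  d <- x - y
  if (all(d == 0)) {
    return(structure(list(label = label, test = "degenerate",
                          statistic = NA_real_, p_value = 1,
                          estimate = 0, dispersion = 0, n = length(d)),
                     class = "paired_test_result"))
  }
  normal <- switch(test,
    paired_t = TRUE,
    wilcoxon = FALSE,
    auto = length(d) >= 8 && dagostino_pearson(d)$p_value >= 0.05)
  if (normal) {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- list(test = "paired_t", statistic = unname(tt$statistic),
                p_value = tt$p.value, estimate = mean(d),
                dispersion = stats::sd(d))
  } else {
    dz <- d[d != 0]
    wt <- suppressWarnings(
      stats::wilcox.test(dz, exact = length(dz) <= 25, correct = TRUE))
    res <- list(test = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value, estimate = stats::median(d),
                dispersion = stats::IQR(d))
  }
  structure(c(list(label = label), res, list(n = length(d))),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result> %s: %s, estimate %.3g, p = %.3g (n = %d)\n",
              x$label, x$test, x$estimate, x$p_value, x$n))
  invisible(x)
}

#' Pearson correlation with two-sided t-based p value
#'
#' @param x,y numeric vectors of equal length >= 3 with finite values and
#'   non-zero variance.
#' @return a list with `r`, `p_value` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need paired vectors of length >= 3", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Sample size for a paired two-sided t test (noncentral t)
#'
#' Smallest number of pairs whose two-sided paired t test at level `alpha`
#' reaches the requested power against a mean difference `delta` with
#' standard deviation of change `sd_change`, computed from the noncentral t
#' distribution (noncentrality `sqrt(n) * delta / sd_change`), not the
#' normal approximation.
#'
#' @param delta detectable mean paired difference.
#' @param sd_change standard deviation of the paired differences.
#' @param power target power, in (0, 1).
#' @param alpha two-sided significance level, in (0, 1).
#' @param n_max search cap.
#' @return required number of pairs (integer, >= 2).
#' @export
#' @examples
#' sample_size_paired(1.0, 1.5, 0.80, 0.05) # 20
sample_size_paired <- function(delta, sd_change, power = 0.80, alpha = 0.05,
                               n_max = 1e6) {
  if (!(delta > 0) || !(sd_change > 0)) {
    stop("`delta` and `sd_change` must be positive", call. = FALSE)
  }
  if (!(power > 0 && power < 1) || !(alpha > 0 && alpha < 1)) {
    stop("`power` and `alpha` must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  for (n in 2:n_max) {
    df <- n - 1
    crit <- stats::qt(1 - alpha / 2, df)
    ncp <- sqrt(n) * delta / sd_change
    pow <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
    if (pow >= power) return(n)
  }
  stop("requested power not attainable within `n_max` pairs", call. = FALSE)
}
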