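# Correlation layer: bootstrap Pearson confidence intervals with
# interpretive bands, Zou's confidence interval for the difference of two
# dependent overlapping correlations, and Holm-Bonferroni adjustment.

#' Interpretive band for a correlation magnitude
#'
#' Cutpoints: below 0.10 negligible, 0.10-0.39 weak, 0.40-0.69 moderate,
#' 0.70-0.89 strong, 0.90-1.00 very strong.
#' @param r Correlation coefficient(s).
#' @return Character vector of band labels.
#' @export
correlation_band <- function(r) {
  a <- abs(r)
  cut(a, breaks = c(-Inf, 0.10, 0.40, 0.70, 0.90, Inf), right = FALSE,
      labels = c("negligible", "weak", "moderate", "strong", "very strong")) |>
    as.character()
}

#' Pearson correlation with bootstrap percentile confidence interval
#'
#' @param x,y Paired numeric vectors (n >= 4, finite).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Seed for the resampling.
#' @return A `phenomap_cor` with `r`, `n`, `ci_low`, `ci_high`, `n_boot`,
#'   two-sided `p`, and `band_label`.
#' @export
pearson_bootstrap_ci <- function(x, y, n_boot = 10000L, conf_level = 0.95,
                                 seed = 1L) {
  if (length(x) != length(y)) stop_validation("x and y must be paired")
  n <- length(x)
  if (n < 4L) stop_validation("need n >= 4")
  assert_finite(x, "x"); assert_finite(y, "y")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_validation("zero variance: correlation undefined")
  }
  r <- stats::cor(x, y)
  p <- stats::cor.test(x, y)$p.value
  alpha <- 1 - conf_level
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(stats::cor(x[idx], y[idx]))
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]  # degenerate resamples (zero variance) dropped
  ci <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(
    list(r = r, n = n, ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
         p = p, band_label = correlation_band(r)),
    class = "phenomap_cor"
  )
}

#' @export
print.phenomap_cor <- function(x, ...) {
  cat(sprintf("r = %.3f (%s), 95%% bootstrap CI [%.3f, %.3f], n = %d, p = %.3g\n",
              x$r, x$band_label, x$ci_low, x$ci_high, x$n, x$p))
  invisible(x)
}

#' Zou confidence interval for two dependent overlapping correlations
#'
#' Compares `cor(j, k)` with `cor(j, h)` — two correlations sharing the
#' variable `j` (e.g. one clinical variable against two imaging measures)
#' measured on the same subjects. The confidence interval for the
#' difference is assembled from the Fisher-z interval endpoints of each
#' correlation together with their estimated co-dependence, which is a
#' function of the correlation `cor(k, h)` between the non-shared
#' variables (Zou 2007). The null of equal correlations is rejected when
#' the interval excludes zero.
#'
#' @param x_j Shared variable (numeric vector).
#' @param x_k,x_h The two variables whose correlations with `x_j` are
#'   compared.
#' @param conf_level Confidence level (default 0.95).
#' @return A `phenomap_cor_diff` with `r_jk`, `r_jh`, `r_kh`, `diff`,
#'   `ci_low`, `ci_high`, `significant`.
#' @export
zou_correlation_difference <- function(x_j, x_k, x_h, conf_level = 0.95) {
  n <- length(x_j)
  if (length(x_k) != n || length(x_h) != n) stop_validation("inputs must be equal length")
  if (n < 4L) stop_validation("need n >= 4")
  assert_finite(x_j, "x_j"); assert_finite(x_k, "x_k"); assert_finite(x_h, "x_h")
  r_jk <- stats::cor(x_j, x_k)
  r_jh <- stats::cor(x_j, x_h)
  r_kh <- stats::cor(x_k, x_h)
  if (abs(r_jk) >= 1 || abs(r_jh) >= 1) {
    abort_phenomap("|r| = 1: Fisher z transform diverges", "phenomap_numerical_error")
  }
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_z <- 1 / sqrt(n - 3)
  fisher_ci <- function(r) {
    z <- atanh(r)
    tanh(c(z - zcrit * se_z, z + zcrit * se_z))
  }
  ci1 <- fisher_ci(r_jk)  # (l1, u1)
  ci2 <- fisher_ci(r_jh)  # (l2, u2)
  # correlation between the two sample correlations (overlapping case)
  corr_num <- (r_kh - 0.5 * r_jk * r_jh) *
    (1 - r_jk^2 - r_jh^2 - r_kh^2) + r_kh^3
  corr_den <- (1 - r_jk^2) * (1 - r_jh^2)
  c12 <- corr_num / corr_den
  c12 <- clip(c12, -1, 1)
  diff <- r_jk - r_jh
  L <- diff - sqrt((r_jk - ci1[1])^2 + (ci2[2] - r_jh)^2 -
                     2 * c12 * (r_jk - ci1[1]) * (ci2[2] - r_jh))
  U <- diff + sqrt((ci1[2] - r_jk)^2 + (r_jh - ci2[1])^2 -
                     2 * c12 * (ci1[2] - r_jk) * (r_jh - ci2[1]))
  structure(
    list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n, diff = diff,
         ci_low = L, ci_high = U, conf_level = conf_level,
         significant = (L > 0 || U < 0)),
    class = "phenomap_cor_diff"
  )
}

#' @export
print.phenomap_cor_diff <- function(x, ...) {
  cat(sprintf("r_jk - r_jh = %.3f - %.3f = %.3f, %.0f%% CI [%.3f, %.3f] -> %s\n",
              x$r_jk, x$r_jh, x$diff, 100 * x$conf_level, x$ci_low, x$ci_high,
              if (x$significant) "correlations differ" else "no difference"))
  invisible(x)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Validating wrapper around the standard step-down procedure; adjusted
#' values are monotone in the sorted order, capped at 1, and returned in
#' the original order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_validation("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}
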