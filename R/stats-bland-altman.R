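# Regression-based Bland-Altman agreement: when the difference between two
# measurement methods is not constant over the measurement range (even
# after log transformation), the bias is modelled as a linear function of
# the pairwise average and the limits of agreement follow the fitted line.

#' Regression-based Bland-Altman limits of agreement
#'
#' Computes per-pair differences `D` and averages `A` (optionally on the
#' log scale), fits the bias regression `D = a + b * A` by ordinary least
#' squares, and places the 95% limits of agreement at the fitted line
#' plus/minus `1.96 * SD(residuals)` (constant-width band). A
#' variable-width band, obtained by regressing the absolute residuals on
#' `A` and scaling by `sqrt(pi / 2)`, is also reported for use when the
#' residual spread itself drifts with the magnitude.
#'
#' With `scale = "log"`, pairs where either method is zero or negative
#' are excluded (their count is reported) rather than offset, keeping the
#' transform faithful.
#'
#' @param method_a,method_b Paired measurements from the two methods.
#' @param scale `"raw"` or `"log"` (natural log).
#' @param loa_z Quantile multiplier for the band (default 1.96).
#' @return A `phenomap_ba` with `bias_intercept`, `bias_slope`,
#'   `loa_halfwidth`, the variable-width coefficients, residual SD, the
#'   per-point `D` and `A`, and `n_excluded`.
#' @export
bland_altman_regression_loa <- function(method_a, method_b,
                                        scale = c("raw", "log"),
                                        loa_z = 1.96) {
  scale <- match.arg(scale)
  if (length(method_a) != length(method_b)) stop_validation("inputs must be paired")
  assert_finite(method_a, "method_a"); assert_finite(method_b, "method_b")
  n_excluded <- 0L
  if (scale == "log") {
    ok <- method_a > 0 & method_b > 0
    n_excluded <- sum(!ok)
    method_a <- log(method_a[ok])
    method_b <- log(method_b[ok])
  }
  if (length(method_a) < 10L) stop_validation("need at least 10 usable pairs")
  D <- method_a - method_b
  A <- (method_a + method_b) / 2
  fit <- stats::lm(D ~ A)
  res <- stats::residuals(fit)
  sd_res <- stats::sd(res)
  # closed-form OLS standard errors (vcov.lm warns on near-perfect fits)
  Xd <- cbind(1, A)
  coef_se <- sqrt(diag(solve(crossprod(Xd))) * sum(res^2) / (length(D) - 2))
  # variable-width option: E|res| regressed on A, scaled to an SD estimate
  vw <- stats::lm(abs(res) ~ A)
  structure(
    list(scale = scale,
         bias_intercept = unname(stats::coef(fit)[1]),
         bias_slope = unname(stats::coef(fit)[2]),
         coef_se = unname(coef_se),
         loa_halfwidth = loa_z * sd_res,
         residual_sd = sd_res,
         varwidth_intercept = unname(stats::coef(vw)[1]) * sqrt(pi / 2) * loa_z,
         varwidth_slope = unname(stats::coef(vw)[2]) * sqrt(pi / 2) * loa_z,
         D = D, A = A, n = length(D), n_excluded = n_excluded,
         loa_z = loa_z),
    class = "phenomap_ba"
  )
}

#' @export
print.phenomap_ba <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s scale, n = %d%s):\n", x$scale, x$n,
              if (x$n_excluded > 0) sprintf(", %d pairs excluded", x$n_excluded) else ""))
  cat(sprintf("  D = %.2f + %.2f A  +/- %.2f\n",
              x$bias_intercept, x$bias_slope, x$loa_halfwidth))
  invisible(x)
}
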