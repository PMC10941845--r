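# Linear mixed models with a random study-site intercept, nested-model
# likelihood-ratio tests, and adjusted conditional R-squared.

# Nakagawa & Schielzeth conditional R^2 for a random-intercept model:
# (fixed-effect variance + random-intercept variance) / total variance;
# the Ezekiel-style adjustment 1 - (1 - R2)(n - 1)/(n - p - 1) discounts
# the number of fixed regressors.
conditional_r2 <- function(fit) {
  var_f <- stats::var(as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_re <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
  var_res <- stats::sigma(fit)^2
  r2 <- (var_f + var_re) / (var_f + var_re + var_res)
  n <- stats::nobs(fit)
  p <- length(lme4::fixef(fit)) - 1L
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  c(conditional_r2 = r2, adjusted_conditional_r2 = max(0, min(1, adj)))
}

#' Fit nested linear mixed models and compare by likelihood-ratio test
#'
#' Fits a baseline and an extended random-intercept model (random term
#' for study site) by maximum likelihood, so the nested-model
#' likelihood-ratio test is valid, and reports the conditional
#' R-squared of each fit adjusted for the number of fixed regressors.
#'
#' @param data Data frame holding outcome, predictors and site labels.
#' @param outcome Name of the outcome column.
#' @param baseline Character vector of baseline fixed-effect terms.
#' @param extended Character vector of extended fixed-effect terms; must
#'   be a superset of `baseline`.
#' @param site Name of the site column (default `"site_id"`).
#' @return A `phenomap_lmm` with both fits' fixed-effect tables, variance
#'   components, conditional/adjusted R-squared, the LRT statistic, its
#'   degrees of freedom, and `lrt_p`.
#' @export
fit_lmm_and_lrt <- function(data, outcome, baseline, extended,
                            site = "site_id") {
  if (!all(baseline %in% extended)) {
    stop_validation("extended predictor set must contain the baseline set")
  }
  if (!site %in% names(data)) stop_validation(sprintf("no site column '%s'", site))
  site_tab <- table(data[[site]])
  if (length(site_tab) < 2L || any(site_tab < 2L)) {
    stop_validation("need >= 2 sites with >= 2 subjects each")
  }
  data[[site]] <- factor(data[[site]])
  mk_formula <- function(terms) {
    stats::as.formula(sprintf(
      "%s ~ %s + (1 | %s)", outcome,
      if (length(terms)) paste(terms, collapse = " + ") else "1", site
    ))
  }
  fit_ml <- function(terms) {
    lme4::lmer(mk_formula(terms), data = data, REML = FALSE)
  }
  fit0 <- fit_ml(baseline)
  fit1 <- fit_ml(extended)
  lrt_stat <- 2 * (as.numeric(stats::logLik(fit1)) - as.numeric(stats::logLik(fit0)))
  df <- length(lme4::fixef(fit1)) - length(lme4::fixef(fit0))
  if (df < 1L) stop_validation("extended model adds no fixed effects")
  lrt_p <- stats::pchisq(max(0, lrt_stat), df = df, lower.tail = FALSE)
  describe <- function(fit) {
    co <- summary(fit)$coefficients
    vc <- lme4::VarCorr(fit)
    list(
      fixed = data.frame(term = rownames(co), estimate = co[, "Estimate"],
                         se = co[, "Std. Error"], row.names = NULL),
      site_variance = vc[[1]][1, 1],
      residual_variance = stats::sigma(fit)^2,
      loglik = as.numeric(stats::logLik(fit)),
      r2 = conditional_r2(fit),
      singular = lme4::isSingular(fit)
    )
  }
  structure(
    list(baseline = describe(fit0), extended = describe(fit1),
         baseline_fit = fit0, extended_fit = fit1,
         lrt_statistic = lrt_stat, lrt_df = df, lrt_p = lrt_p,
         outcome = outcome,
         added_terms = setdiff(extended, baseline)),
    class = "phenomap_lmm"
  )
}

#' @export
print.phenomap_lmm <- function(x, ...) {
  cat(sprintf("LMM for %s: + %s\n", x$outcome, paste(x$added_terms, collapse = ", ")))
  cat(sprintf("  adj. conditional R2: %.3f -> %.3f; LRT chi2(%d) = %.2f, p = %.3g\n",
              x$baseline$r2[["adjusted_conditional_r2"]],
              x$extended$r2[["adjusted_conditional_r2"]],
              x$lrt_df, x$lrt_statistic, x$lrt_p))
  if (x$extended$singular) cat("  note: extended fit is singular\n")
  invisible(x)
}
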