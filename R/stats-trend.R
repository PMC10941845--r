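# Ordered-trend testing across severity stages and post-hoc pairwise
# comparisons.

jt_statistic <- function(groups) {
  k <- length(groups)
  jt <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      xi <- groups[[i]]
      yj <- groups[[j]]
      cmp <- outer(xi, yj, FUN = function(a, b) (a < b) + 0.5 * (a == b))
      jt <- jt + sum(cmp)
    }
  }
  jt
}

# Tie-corrected null variance of the JT statistic (Hollander & Wolfe).
jt_null_moments <- function(groups) {
  ns <- lengths(groups)
  N <- sum(ns)
  pooled <- unlist(groups, use.names = FALSE)
  ties <- table(pooled)
  t1 <- sum(ties * (ties - 1) * (2 * ties + 5))
  t2 <- sum(ties * (ties - 1) * (ties - 2))
  t3 <- sum(ties * (ties - 1))
  n1 <- sum(ns * (ns - 1) * (2 * ns + 5))
  n2 <- sum(ns * (ns - 1) * (ns - 2))
  n3 <- sum(ns * (ns - 1))
  expected <- (N^2 - sum(ns^2)) / 4
  v <- (N * (N - 1) * (2 * N + 5) - n1 - t1) / 72
  if (N > 2) v <- v + n2 * t2 / (36 * N * (N - 1) * (N - 2))
  v <- v + n3 * t3 / (8 * N * (N - 1))
  list(expected = expected, variance = v)
}

#' Jonckheere-Terpstra test for an ordered trend
#'
#' Tests for a monotone trend in location over groups given in increasing
#' order (here, severity stages). The statistic counts concordant
#' cross-group pairs, with ties counted one half. The p-value uses the
#' normal approximation with tie-corrected variance and continuity
#' correction, or a Monte-Carlo permutation null when
#' `p_method = "permutation"`.
#'
#' @param groups List of numeric vectors, one per ordered group.
#' @param alternative `"increasing"` (default), `"decreasing"`, or
#'   `"two.sided"`.
#' @param p_method `"normal"` (default) or `"permutation"`.
#' @param n_perm Permutation count for `p_method = "permutation"`.
#' @param seed Seed for the permutation null.
#' @return A `phenomap_jt` with `statistic`, `expected`, `variance`, `z`,
#'   `p`, and the chosen `alternative`.
#' @export
#' @examples
#' jonckheere_terpstra(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
jonckheere_terpstra <- function(groups,
                                alternative = c("increasing", "decreasing", "two.sided"),
                                p_method = c("normal", "permutation"),
                                n_perm = 10000L, seed = 1L) {
  alternative <- match.arg(alternative)
  p_method <- match.arg(p_method)
  if (length(groups) < 2L) stop_validation("need at least 2 ordered groups")
  if (any(lengths(groups) == 0L)) stop_validation("every group must be non-empty")
  lapply(groups, assert_finite, what = "group values")
  jt <- jt_statistic(groups)
  mom <- jt_null_moments(groups)
  if (mom$variance <= 0) {
    abort_phenomap("all values identical: JT variance is zero",
                   "phenomap_degenerate_error")
  }
  z <- (jt - mom$expected) / sqrt(mom$variance)
  if (p_method == "normal") {
    # continuity correction for the discrete statistic:
    # P(JT >= jt) ~ 1 - Phi((jt - 1/2 - E)/sd), P(JT <= jt) ~ Phi((jt + 1/2 - E)/sd)
    sd0 <- sqrt(mom$variance)
    p_up <- stats::pnorm((jt - 0.5 - mom$expected) / sd0, lower.tail = FALSE)
    p_dn <- stats::pnorm((jt + 0.5 - mom$expected) / sd0)
    p <- switch(alternative,
                increasing = p_up,
                decreasing = p_dn,
                two.sided = min(1, 2 * min(p_up, p_dn)))
  } else {
    ns <- lengths(groups)
    pooled <- unlist(groups, use.names = FALSE)
    idx_end <- cumsum(ns)
    idx_start <- c(1L, idx_end[-length(ns)] + 1L)
    p <- with_seed(seed, {
      perm_stats <- vapply(seq_len(n_perm), function(r) {
        shuf <- sample(pooled)
        jt_statistic(lapply(seq_along(ns), function(g) {
          shuf[idx_start[g]:idx_end[g]]
        }))
      }, numeric(1))
      switch(alternative,
             increasing = (1 + sum(perm_stats >= jt)) / (n_perm + 1),
             decreasing = (1 + sum(perm_stats <= jt)) / (n_perm + 1),
             two.sided = min(1, 2 * min(
               (1 + sum(perm_stats >= jt)) / (n_perm + 1),
               (1 + sum(perm_stats <= jt)) / (n_perm + 1)
             )))
    })
  }
  structure(
    list(statistic = jt, expected = mom$expected, variance = mom$variance,
         z = z, p = p, alternative = alternative, p_method = p_method),
    class = "phenomap_jt"
  )
}

#' @export
print.phenomap_jt <- function(x, ...) {
  cat(sprintf("Jonckheere-Terpstra: JT = %.1f (E = %.1f, z = %.2f), p = %.4g [%s, %s]\n",
              x$statistic, x$expected, x$z, x$p, x$alternative, x$p_method))
  invisible(x)
}

#' Tukey honest-significant-difference post-hoc comparisons
#'
#' Studentized-range-adjusted pairwise comparisons after a one-way
#' analysis of variance, used here for pairwise severity-stage contrasts
#' following a significant trend.
#'
#' @param values Numeric outcome vector.
#' @param group Group labels (coerced to factor).
#' @return Data frame with one row per pair: `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_posthoc <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop_validation("need at least 2 groups")
  if (any(table(group) < 2L)) stop_validation("every group needs n >= 2")
  fit <- stats::aov(values ~ group, data = data.frame(values = values, group = group))
  tk <- stats::TukeyHSD(fit)$group
  out <- data.frame(
    comparison = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
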