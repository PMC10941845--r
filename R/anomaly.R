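# Density-based regional anomaly scoring: a reference density is fitted to
# latent features of healthy lung regions, every patch is scored by its
# negative log-likelihood (NLL, nats) under that reference, patient scores
# aggregate patch scores, and anomaly map volumes are rendered after
# 5th/95th-percentile min-max normalization across the analysis cohort.

#' Select reference ("normal") patches
#'
#' The normative baseline is built from lung regions with less than
#' `max_emph_pct` percent emphysema (patch-level LAA-950 on the
#' inspiratory patch) belonging to subjects without airflow obstruction
#' (never-smoker controls and GOLD 0).
#'
#' @param features A `phenomap_features` object (see [embed_cohort()]).
#' @param max_emph_pct Emphysema threshold in percent (default 1).
#' @param healthy_stages Stages considered free of airflow obstruction.
#' @return Logical vector over patches: `TRUE` for reference patches.
#' @export
select_reference_patches <- function(features, max_emph_pct = 1,
                                     healthy_stages = c("control", "GOLD0")) {
  sel <- features$meta$stage %in% healthy_stages &
    features$meta$emph_pct < max_emph_pct
  if (!any(sel)) {
    stop_config(paste(
      "empty reference set: no low-emphysema patches from healthy subjects;",
      "generate a larger cohort or relax max_emph_pct"
    ))
  }
  sel
}

# PCA-whitening transform fitted on the reference features; keeps at most
# `max_dims` components with non-negligible variance so covariance
# estimation downstream stays well-posed.
fit_whitener <- function(X, max_dims = 32L) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > max(pc$sdev) * 1e-8)
  keep <- keep[seq_len(min(length(keep), max_dims))]
  list(center = pc$center, rotation = pc$rotation[, keep, drop = FALSE],
       sdev = pc$sdev[keep])
}

apply_whitener <- function(wh, X) {
  Z <- sweep(X, 2, wh$center) %*% wh$rotation
  sweep(Z, 2, wh$sdev, "/")
}

#' Fit the reference density of normal lung features
#'
#' Fits either a single multivariate Gaussian or a Gaussian mixture
#' (full covariances, component count selected by minimum BIC over
#' `k_range`) to the reference feature set, optionally after
#' PCA-whitening to at most `whiten_dims` dimensions. A small ridge is
#' added to every covariance for numerical stability.
#'
#' @param X Numeric matrix of reference features (rows = patches).
#' @param family `"gaussian"` or `"gaussian_mixture"`.
#' @param k_range Candidate component counts for the mixture (default 1:8).
#' @param whiten Apply PCA-whitening first (default TRUE).
#' @param whiten_dims Maximum whitened dimensionality (default 32).
#' @param ridge Covariance ridge (default 1e-6).
#' @param seed Seed controlling mixture initialization.
#' @return A `phenomap_density` with weights, means, covariance Cholesky
#'   factors, the whitening transform, and fit diagnostics (`loglik`,
#'   `bic`, `bic_table`).
#' @export
fit_reference_density <- function(X, family = c("gaussian_mixture", "gaussian"),
                                  k_range = 1:8, whiten = TRUE,
                                  whiten_dims = 32L, ridge = 1e-6,
                                  seed = 1L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  wh <- NULL
  if (whiten) {
    wh <- fit_whitener(X, whiten_dims)
    Z <- apply_whitener(wh, X)
  } else {
    Z <- X
  }
  n <- nrow(Z)
  d <- ncol(Z)
  if (n <= d) {
    stop_validation(sprintf(
      "need more reference patches (%d) than feature dimensions (%d)", n, d))
  }
  if (family == "gaussian") {
    mu <- colMeans(Z)
    S <- stats::cov(Z) + diag(ridge, d)
    dens <- make_density(1, matrix(mu, nrow = 1), list(S), wh, family)
    dens$loglik <- sum(score_matrix(dens, Z, raw = TRUE))
    npar <- d + d * (d + 1) / 2
    dens$bic <- -2 * dens$loglik + npar * log(n)
    dens$bic_table <- data.frame(k = 1L, bic = dens$bic)
    return(dens)
  }
  fits <- with_seed(seed, {
    lapply(k_range, function(k) fit_mclust_vvv(Z, k))
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    abort_phenomap(
      "mixture fitting failed for every k; covariance may be singular despite ridge",
      "phenomap_numerical_error"
    )
  }
  # mclust BIC = 2*loglik - npar*log(n) (higher is better); convert to the
  # conventional minimized form for reporting.
  bics <- vapply(fits, function(f) if (is.null(f)) Inf else -f$bic, numeric(1))
  best <- which.min(bics)
  fit <- fits[[best]]
  k <- fit$G
  means <- t(fit$parameters$mean)
  if (k == 1L && nrow(means) != 1L) means <- matrix(fit$parameters$mean, nrow = 1)
  covs <- lapply(seq_len(k), function(g) {
    fit$parameters$variance$sigma[, , g] + diag(ridge, d)
  })
  dens <- make_density(fit$parameters$pro, means, covs, wh, family)
  dens$loglik <- fit$loglik
  dens$bic <- bics[best]
  dens$bic_table <- data.frame(k = k_range, bic = bics)
  dens
}

# Full-covariance Gaussian mixture fit. Mclust resolves its helpers in
# the calling frame, so the call is evaluated inside an environment whose
# parent is the mclust namespace; this works with mclust loaded but not
# attached. Returns NULL when the fit fails or degenerates.
fit_mclust_vvv <- function(Z, k) {
  env <- list2env(list(.Z = Z, .k = as.integer(k)), parent = asNamespace("mclust"))
  fit <- tryCatch(
    eval(quote(Mclust(.Z, G = .k, modelNames = "VVV", verbose = FALSE)), envir = env),
    error = function(e) NULL
  )
  if (is.null(fit) || is.null(fit$parameters)) NULL else fit
}

make_density <- function(weights, means, covs, whitener, family) {
  weights <- weights / sum(weights)
  chols <- lapply(covs, function(S) chol(S))
  structure(
    list(family = family, n_components = length(weights), weights = weights,
         means = means, covariances = covs, chols = chols,
         whitener = whitener, dim = ncol(means)),
    class = "phenomap_density"
  )
}

#' @export
print.phenomap_density <- function(x, ...) {
  cat(sprintf("<reference density> %s, %d component(s), %d dims, BIC %.1f\n",
              x$family, x$n_components, x$dim, x$bic %||% NA_real_))
  invisible(x)
}

# Gaussian log-density via Cholesky; x rows in whitened space.
gaussian_logpdf <- function(Z, mu, cholS) {
  d <- ncol(Z)
  diff <- sweep(Z, 2, mu)
  y <- backsolve(cholS, t(diff), transpose = TRUE)
  maha <- colSums(y^2)
  logdet <- 2 * sum(log(diag(cholS)))
  -0.5 * (d * log(2 * pi) + logdet + maha)
}

score_matrix <- function(density, Z, raw = FALSE) {
  comp <- vapply(seq_len(density$n_components), function(g) {
    gaussian_logpdf(Z, density$means[g, ], density$chols[[g]]) +
      log(density$weights[g])
  }, numeric(nrow(Z)))
  comp <- matrix(comp, nrow = nrow(Z))
  m <- apply(comp, 1, max)
  ll <- m + log(rowSums(exp(comp - m)))
  if (raw) ll else -ll
}

#' Score patches by negative log-likelihood
#'
#' @param density A `phenomap_density` from [fit_reference_density()].
#' @param features A `phenomap_features` object or a bare feature matrix
#'   in the same space the density was fitted on.
#' @return Numeric vector of per-patch NLL scores (nats); larger = more
#'   anomalous.
#' @export
score_patches <- function(density, features) {
  X <- if (inherits(features, "phenomap_features")) features$matrix else as.matrix(features)
  if (!is.null(density$whitener)) {
    if (ncol(X) != length(density$whitener$center)) {
      stop_config("feature dimension does not match the density's whitening transform")
    }
    Z <- apply_whitener(density$whitener, X)
  } else {
    if (ncol(X) != density$dim) stop_config("feature dimension mismatch")
    Z <- X
  }
  score_matrix(density, Z)
}

#' Aggregate patch scores to a patient-level anomaly score
#'
#' @param patch_scores Numeric vector of patch NLLs for one subject.
#' @param method `"mean"` (default), `"median"` or `"max"`.
#' @return Scalar patient anomaly score.
#' @export
aggregate_patient_score <- function(patch_scores, method = c("mean", "median", "max")) {
  method <- match.arg(method)
  if (length(patch_scores) == 0L) stop_validation("no patch scores to aggregate")
  assert_finite(patch_scores, "patch scores")
  switch(method,
         mean = mean(patch_scores),
         median = stats::median(patch_scores),
         max = max(patch_scores))
}

#' Render a normalized anomaly map volume
#'
#' Every lung voxel receives the mean NLL of all patches containing it,
#' then scores are min-max normalized to `[0, 1]` using cohort-wide
#' bounds, conventionally the 5th and 95th percentiles of the analysis
#' cohort's patch score distribution; values outside are clipped. Non-lung
#' voxels are 0.
#'
#' @param patch_scores Scores for this subject's patches, in grid order.
#' @param grid The subject's [plan_patches()] grid.
#' @param mask Logical lung mask, same shape the grid was planned on.
#' @param bounds Length-2 numeric `(p5, p95)` normalization bounds.
#' @return Numeric 3D array in `[0, 1]`.
#' @export
render_anomaly_map <- function(patch_scores, grid, mask, bounds) {
  if (length(patch_scores) != nrow(grid$origins)) {
    stop_validation("one score per planned patch required")
  }
  if (!identical(dim(mask), grid$grid_shape)) {
    stop_dimension("mask shape differs from the grid's planning shape")
  }
  if (bounds[2] <= bounds[1]) {
    warning("degenerate normalization bounds (p95 <= p5); returning all-zero map")
    return(array(0, dim = dim(mask)))
  }
  acc <- array(0, dim = dim(mask))
  cnt <- array(0L, dim = dim(mask))
  ext <- grid$extent
  for (i in seq_len(nrow(grid$origins))) {
    o <- grid$origins[i, ]
    ix <- (o[1] + 1L):(o[1] + ext[1])
    iy <- (o[2] + 1L):(o[2] + ext[2])
    iz <- (o[3] + 1L):(o[3] + ext[3])
    acc[ix, iy, iz] <- acc[ix, iy, iz] + patch_scores[i]
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
  }
  raw <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), 0)
  norm <- clip((raw - bounds[1]) / (bounds[2] - bounds[1]), 0, 1)
  norm[!mask | cnt == 0L] <- 0
  norm
}

#' Run the full anomaly-scoring stage over a cohort
#'
#' Selects reference patches, fits the reference density, scores all
#' patches, aggregates per-subject scores, and computes the cohort-wide
#' 5th/95th-percentile normalization bounds.
#'
#' @param features A `phenomap_features` object.
#' @param family,k_range,whiten,whiten_dims,seed Passed to
#'   [fit_reference_density()].
#' @param aggregate Patient aggregation method (default `"mean"`).
#' @param percentiles Normalization percentiles (default `c(0.05, 0.95)`).
#' @return A `phenomap_anomaly` with `patch_scores`, `patient` (data
#'   frame of per-subject scores), the `density`, `reference_mask` and
#'   `normalization_bounds`.
#' @export
anomaly_stage <- function(features, family = "gaussian_mixture", k_range = 1:4,
                          whiten = TRUE, whiten_dims = 16L, seed = 1L,
                          aggregate = "mean", percentiles = c(0.05, 0.95)) {
  ref <- select_reference_patches(features)
  density <- fit_reference_density(features$matrix[ref, , drop = FALSE],
                                   family = family, k_range = k_range,
                                   whiten = whiten, whiten_dims = whiten_dims,
                                   seed = seed)
  scores <- score_patches(density, features)
  patient <- stats::aggregate(
    scores,
    by = list(subject_id = features$meta$subject_id),
    FUN = function(s) aggregate_patient_score(s, aggregate)
  )
  names(patient)[2] <- "patient_score"
  info <- unique(features$meta[, c("subject_id", "stage", "site_id")])
  patient <- merge(info, patient, by = "subject_id", sort = FALSE)
  bounds <- stats::quantile(scores, percentiles, names = FALSE)
  structure(
    list(patch_scores = scores, patient = patient, density = density,
         reference_mask = ref, normalization_bounds = bounds,
         aggregate = aggregate),
    class = "phenomap_anomaly"
  )
}

#' @export
print.phenomap_anomaly <- function(x, ...) {
  cat(sprintf("<anomaly stage> %d patches (%d reference), %d subjects, bounds [%.2f, %.2f]\n",
              length(x$patch_scores), sum(x$reference_mask), nrow(x$patient),
              x$normalization_bounds[1], x$normalization_bounds[2]))
  invisible(x)
}
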