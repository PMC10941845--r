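# Latent-structure analysis: PCA with principled component retention
# (Horn's parallel analysis + Kaiser criterion), cluster analysis with
# multi-metric model selection, per-subject cluster volumes, and cluster
# label maps.

#' PCA with Horn's parallel analysis and Kaiser retention
#'
#' Mean-centers (optionally scales) the feature matrix and computes its
#' principal components. Component retention is decided on the
#' correlation-scale eigenvalue spectrum: Horn's parallel analysis keeps
#' components whose eigenvalue exceeds the chosen percentile of the
#' position-matched eigenvalues obtained from `n_pa_reps` same-shape
#' standard-normal surrogate matrices; the Kaiser criterion keeps
#' eigenvalues above 1. `n_retained` follows Horn; the Kaiser count is
#' reported alongside.
#'
#' @param X Numeric matrix (rows = observations).
#' @param n_pa_reps Surrogate replicates for parallel analysis (default 100).
#' @param pa_percentile Surrogate eigenvalue percentile (default 0.95).
#' @param scale. Scale columns to unit variance before the PCA projection
#'   (default FALSE; retention always uses the correlation scale).
#' @param seed Seed for the surrogate draws.
#' @return A `phenomap_pca` with loadings, scores, eigenvalues (data and
#'   surrogate threshold curves), `n_retained`, and `n_kaiser`.
#' @export
fit_pca_with_retention <- function(X, n_pa_reps = 100L, pa_percentile = 0.95,
                                   scale. = FALSE, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_validation("need at least 2 rows for PCA")
  keep_cols <- which(apply(X, 2, stats::sd) > 1e-12)
  Xe <- X[, keep_cols, drop = FALSE]
  n <- nrow(Xe)
  d <- ncol(Xe)
  pc <- stats::prcomp(Xe, center = TRUE, scale. = scale.)
  # retention on the correlation scale
  eig_corr <- eigen(stats::cor(Xe), symmetric = TRUE, only.values = TRUE)$values
  surrogate <- with_seed(seed, {
    t(vapply(seq_len(n_pa_reps), function(r) {
      R <- matrix(stats::rnorm(n * d), n, d)
      eigen(stats::cor(R), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(d)))
  })
  pa_thresholds <- apply(surrogate, 2, stats::quantile, probs = pa_percentile)
  n_horn <- as.integer(sum(cumprod(eig_corr > pa_thresholds)))  # contiguous from the top
  n_kaiser <- as.integer(sum(eig_corr > 1))
  n_retained <- max(1L, n_horn)
  structure(
    list(loadings = pc$rotation, scores = pc$x,
         eigenvalues = pc$sdev^2, eig_corr = eig_corr,
         pa_thresholds = pa_thresholds, n_horn = n_horn,
         n_kaiser = n_kaiser, n_retained = n_retained,
         center = pc$center, scale = pc$scale, kept_columns = keep_cols),
    class = "phenomap_pca"
  )
}

#' @export
print.phenomap_pca <- function(x, ...) {
  cat(sprintf("<PCA> %d components; Horn retains %d (Kaiser %d)\n",
              length(x$eigenvalues), x$n_horn, x$n_kaiser))
  invisible(x)
}

#' Retained principal-component scores
#' @param pca A `phenomap_pca`.
#' @return Score matrix restricted to the retained components.
#' @export
retained_scores <- function(pca) {
  pca$scores[, seq_len(min(pca$n_retained, ncol(pca$scores))), drop = FALSE]
}

## ---- internal clustering quality metrics ---------------------------------

cluster_silhouette <- function(X, labels) {
  n <- nrow(X)
  if (length(unique(labels)) < 2L) return(NA_real_)
  D <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / n_own
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(D[i, labels == g])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

cluster_davies_bouldin <- function(X, labels) {
  gs <- sort(unique(labels))
  k <- length(gs)
  if (k < 2L) return(NA_real_)
  centroids <- do.call(rbind, lapply(gs, function(g) {
    colMeans(X[labels == g, , drop = FALSE])
  }))
  scatter <- vapply(seq_along(gs), function(gi) {
    pts <- X[labels == gs[gi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, centroids[gi, ])^2)))
  }, numeric(1))
  db <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (scatter[i] + scatter[j]) /
        sqrt(sum((centroids[i, ] - centroids[j, ])^2))
    }, numeric(1)))
  }, numeric(1))
  mean(db)
}

cluster_calinski_harabasz <- function(X, labels) {
  gs <- sort(unique(labels))
  k <- length(gs)
  n <- nrow(X)
  if (k < 2L || k >= n) return(NA_real_)
  overall <- colMeans(X)
  bss <- 0
  wss <- 0
  for (g in gs) {
    pts <- X[labels == g, , drop = FALSE]
    ctr <- colMeans(pts)
    bss <- bss + nrow(pts) * sum((ctr - overall)^2)
    wss <- wss + sum(sweep(pts, 2, ctr)^2)
  }
  (bss / (k - 1)) / (wss / (n - k))
}

## ---- mini-batch k-means ---------------------------------------------------

# Mini-batch k-means (Sculley 2010): k-means++ initialization, per-center
# learning rates 1/count; deterministic given the RNG state. Falls back to
# full batches when n <= batch_size, in which case it converges to the
# ordinary Lloyd fixed point.
mini_batch_kmeans <- function(X, k, batch_size = 1000L, n_iter = 100L) {
  n <- nrow(X)
  if (k >= n) stop_validation("k must be smaller than the number of rows")
  # k-means++ seeding
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L)) {
    probs <- d2 / sum(d2)
    nxt <- sample.int(n, 1L, prob = probs)
    centers[j + 1L, ] <- X[nxt, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j + 1L, ])^2))
  }
  counts <- rep(0, k)
  for (it in seq_len(n_iter)) {
    b <- if (n <= batch_size) seq_len(n) else sample.int(n, batch_size)
    Xb <- X[b, , drop = FALSE]
    a <- nearest_center(Xb, centers)
    for (j in unique(a)) {
      pts <- Xb[a == j, , drop = FALSE]
      for (r in seq_len(nrow(pts))) {
        counts[j] <- counts[j] + 1
        eta <- 1 / counts[j]
        centers[j, ] <- (1 - eta) * centers[j, ] + eta * pts[r, ]
      }
    }
  }
  assignments <- nearest_center(X, centers)
  list(centers = centers, assignments = assignments)
}

nearest_center <- function(X, centers) {
  cross <- X %*% t(centers)
  cn <- rowSums(centers^2)
  d2 <- sweep(-2 * cross, 2, cn, `+`)  # row-wise ||x||^2 omitted (constant)
  max.col(-d2, ties.method = "first")
}

## ---- cluster model selection ----------------------------------------------

#' Cluster latent scores with multi-metric model selection
#'
#' Fits every combination of method (`minibatch_kmeans`,
#' `gaussian_mixture`) and cluster count in `k_range`, evaluates the
#' Silhouette (maximized), Davies-Bouldin (minimized) and
#' Calinski-Harabasz (maximized) indices, and selects the candidate with
#' the lowest mean rank across the three metrics (ties broken toward
#' smaller `k`, then method order). Candidates that produce an empty
#' cluster are refitted with a new seed up to `max_retries` times.
#'
#' @param X Numeric matrix of retained principal-component scores.
#' @param methods Clustering methods to compare.
#' @param k_range Candidate cluster counts (default 2:8).
#' @param batch_size Mini-batch size for k-means (default 1000).
#' @param seed Seed controlling initialization.
#' @param max_retries Seed retries on degenerate fits (default 3).
#' @param silhouette_max_n Subsample size cap for the silhouette/DB/CH
#'   evaluation on large inputs (default 2000).
#' @return A `phenomap_clusters` with `method`, `k`, `assignments`,
#'   `quality`, and the full `selection_table`.
#' @export
cluster_latent <- function(X, methods = c("minibatch_kmeans", "gaussian_mixture"),
                           k_range = 2:8, batch_size = 1000L, seed = 1L,
                           max_retries = 3L, silhouette_max_n = 2000L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(k_range < 2L) || any(k_range >= n)) {
    stop_validation("k_range must lie within [2, n_rows - 1]")
  }
  eval_idx <- if (n > silhouette_max_n) {
    with_seed(derive_seed(seed, 999L), sample.int(n, silhouette_max_n))
  } else seq_len(n)

  fit_one <- function(method, k, attempt) {
    s <- derive_seed(seed, 1000L * attempt + k * 10L + match(method, methods))
    with_seed(s, {
      if (method == "minibatch_kmeans") {
        mini_batch_kmeans(X, k, batch_size = batch_size)$assignments
      } else {
        fit <- fit_mclust_vvv(X, k)
        if (is.null(fit)) NULL else as.integer(fit$classification)
      }
    })
  }

  rows <- list()
  assign_store <- list()
  for (method in methods) {
    for (k in k_range) {
      a <- NULL
      for (attempt in seq_len(max_retries)) {
        a <- fit_one(method, k, attempt)
        if (!is.null(a) && length(unique(a)) == k) break
        a <- NULL
      }
      if (is.null(a)) next
      Xi <- X[eval_idx, , drop = FALSE]
      ai <- a[eval_idx]
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, k = k,
        silhouette = cluster_silhouette(Xi, ai),
        davies_bouldin = cluster_davies_bouldin(Xi, ai),
        calinski_harabasz = cluster_calinski_harabasz(Xi, ai)
      )
      assign_store[[paste(method, k)]] <- a
    }
  }
  if (length(rows) == 0L) {
    abort_phenomap("no clustering candidate produced a non-degenerate fit",
                   "phenomap_numerical_error")
  }
  tab <- do.call(rbind, rows)
  tab$rank_sil <- rank(-tab$silhouette, ties.method = "average")
  tab$rank_db <- rank(tab$davies_bouldin, ties.method = "average")
  tab$rank_ch <- rank(-tab$calinski_harabasz, ties.method = "average")
  tab$mean_rank <- (tab$rank_sil + tab$rank_db + tab$rank_ch) / 3
  ord <- order(tab$mean_rank, tab$k, match(tab$method, methods))
  best <- tab[ord[1], ]
  assignments <- assign_store[[paste(best$method, best$k)]]
  structure(
    list(method = best$method, k = best$k, assignments = assignments,
         quality = c(silhouette = best$silhouette,
                     davies_bouldin = best$davies_bouldin,
                     calinski_harabasz = best$calinski_harabasz),
         selection_table = tab, seed = seed,
         no_structure = is.finite(best$silhouette) && best$silhouette < 0.3),
    class = "phenomap_clusters"
  )
}

#' @export
print.phenomap_clusters <- function(x, ...) {
  cat(sprintf("<clusters> %s, k = %d, silhouette %.3f%s\n", x$method, x$k,
              x$quality[["silhouette"]],
              if (isTRUE(x$no_structure)) " (weak structure)" else ""))
  invisible(x)
}

#' Per-subject relative cluster volumes
#'
#' @param assignments Integer cluster label per patch.
#' @param meta Patch metadata with a `subject_id` column (e.g.
#'   `features$meta`), rows aligned with `assignments`.
#' @param k Number of clusters (defaults to `max(assignments)`).
#' @return Data frame: one row per subject, columns `cluster_1..k` with
#'   fractions of that subject's patches in each cluster (rows sum to 1).
#' @export
cluster_subject_volumes <- function(assignments, meta, k = max(assignments)) {
  if (length(assignments) != nrow(meta)) {
    stop_validation("assignments and metadata must have matching length")
  }
  subjects <- unique(meta$subject_id)
  out <- lapply(subjects, function(sid) {
    a <- assignments[meta$subject_id == sid]
    if (length(a) == 0L) {
      warning(sprintf("subject %s has no patches; excluded", sid))
      return(NULL)
    }
    fr <- tabulate(a, k) / length(a)
    row <- as.data.frame(as.list(fr))
    names(row) <- paste0("cluster_", seq_len(k))
    cbind(data.frame(subject_id = sid, stringsAsFactors = FALSE), row)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Render a cluster label map volume
#'
#' Each lung voxel takes the cluster label of the patch whose center is
#' nearest (Euclidean, ties toward the lowest label); non-lung voxels are 0.
#'
#' @param assignments Integer cluster label per patch of one subject.
#' @param grid That subject's [plan_patches()] grid.
#' @param mask Logical lung mask.
#' @return Integer 3D labelmap.
#' @export
render_cluster_map <- function(assignments, grid, mask) {
  if (length(assignments) != nrow(grid$origins)) {
    stop_validation("one label per patch required")
  }
  if (!identical(dim(mask), grid$grid_shape)) {
    stop_dimension("mask shape differs from the grid's planning shape")
  }
  centers <- sweep(grid$origins, 2, grid$extent / 2, `+`)
  vox <- which(mask, arr.ind = TRUE) - 0.5
  d2 <- matrix(0, nrow(vox), nrow(centers))
  for (j in seq_len(nrow(centers))) {
    d2[, j] <- (vox[, 1] - centers[j, 1])^2 +
      (vox[, 2] - centers[j, 2])^2 +
      (vox[, 3] - centers[j, 3])^2
  }
  ord <- order(assignments)  # ties -> lowest label wins
  nearest <- ord[max.col(-d2[, ord, drop = FALSE], ties.method = "first")]
  out <- array(0L, dim = dim(mask))
  out[mask] <- assignments[nearest]
  out
}
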