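# Exact (O(n^2)) t-SNE for latent-space visualization, with an
# out-of-sample transform that places new points among their nearest
# fitted neighbours. Intended for modest fit-set sizes (hundreds to a few
# thousand rows); the embedding is treated strictly as a visualization.

# Perplexity calibration: binary search of the Gaussian bandwidth per row.
tsne_affinities <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    beta_lo <- -Inf
    beta_hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { h <- 0 } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      err <- h - target
      if (abs(err) < 1e-5) break
      if (err > 0) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_fit <- function(X, perplexity, n_iter, seed) {
  n <- nrow(X)
  # PCA initialization (first two components, scaled small) for stable,
  # seed-reproducible layouts.
  pc <- stats::prcomp(X, center = TRUE, rank. = 2)
  Y <- pc$x[, 1:2, drop = FALSE]
  Y <- Y / stats::sd(Y[, 1]) * 1e-4
  D2 <- as.matrix(stats::dist(X))^2
  P <- tsne_affinities(D2, perplexity)
  gain <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  eta <- 200
  for (it in seq_len(n_iter)) {
    exaggeration <- if (it <= 100) 12 else 1
    momentum <- if (it <= 250) 0.5 else 0.8
    Dy <- as.matrix(stats::dist(Y))^2
    W <- 1 / (1 + Dy)
    diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    M <- (exaggeration * P - Q) * W
    grad <- 4 * (diag(rowSums(M)) %*% Y - M %*% Y)
    gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    inc <- momentum * inc - eta * gain * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' t-SNE embedding with out-of-sample transform
#'
#' Fits a 2-D t-SNE embedding on `fit_features` (e.g. an evaluation set)
#' and places `transform_features` (e.g. a test set) into the fitted map:
#' each new point is embedded at the similarity-weighted mean of the
#' embedding coordinates of its `transform_k` nearest fitted neighbours,
#' with Gaussian weights on the high-dimensional distances. Deterministic
#' given `seed`.
#'
#' @param fit_features Numeric matrix the embedding is fitted on
#'   (>= 50 rows).
#' @param transform_features Optional matrix of new points to place.
#' @param perplexity t-SNE perplexity (default 30, reduced automatically
#'   when the fit set is small).
#' @param n_iter Gradient-descent iterations (default 400).
#' @param transform_k Neighbours used by the transform step (default 10).
#' @param seed Integer seed.
#' @return A `phenomap_tsne` with `fit` (n x 2) and, when requested,
#'   `transform` coordinates.
#' @export
tsne_embed <- function(fit_features, transform_features = NULL,
                       perplexity = 30, n_iter = 400L, transform_k = 10L,
                       seed = 1L) {
  X <- as.matrix(fit_features)
  if (nrow(X) < 50L) stop_validation("t-SNE fit set needs at least 50 rows")
  perplexity <- min(perplexity, (nrow(X) - 1) / 3)
  Y <- with_seed(seed, tsne_fit(X, perplexity, n_iter, seed))
  out <- list(fit = Y, perplexity = perplexity, seed = seed)
  if (!is.null(transform_features)) {
    Z <- as.matrix(transform_features)
    if (ncol(Z) != ncol(X)) stop_validation("transform features dimension mismatch")
    k <- min(transform_k, nrow(X))
    Yt <- matrix(0, nrow(Z), 2)
    for (i in seq_len(nrow(Z))) {
      d2 <- colSums((t(X) - Z[i, ])^2)
      nn <- order(d2)[seq_len(k)]
      sigma2 <- stats::median(d2[nn]) + 1e-12
      w <- exp(-d2[nn] / sigma2)
      w <- w / sum(w)
      Yt[i, ] <- colSums(Y[nn, , drop = FALSE] * w)
    }
    out$transform <- Yt
  }
  structure(out, class = "phenomap_tsne")
}

#' @export
print.phenomap_tsne <- function(x, ...) {
  cat(sprintf("<t-SNE> fit %d points (perplexity %.1f)%s\n", nrow(x$fit),
              x$perplexity,
              if (!is.null(x$transform)) sprintf(", transformed %d", nrow(x$transform)) else ""))
  invisible(x)
}
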