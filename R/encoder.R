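# Optional contrastive patch encoder: a desk-scale linear encoder trained
# with an InfoNCE objective on augmented patch views. It is a small,
# self-contained alternative to the deterministic histogram featurizer,
# exposing the same patch -> fixed-length-vector surface.

# Average-pool a 3D array onto a p x p x p grid (handles any input shape).
pool_patch <- function(arr, p = 5L) {
  d <- dim(arr)
  cuts <- lapply(d, function(n) floor(seq(0, n, length.out = p + 1L)))
  out <- array(0, dim = c(p, p, p))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      for (k in seq_len(p)) {
        xs <- (cuts[[1]][i] + 1L):max(cuts[[1]][i + 1L], cuts[[1]][i] + 1L)
        ys <- (cuts[[2]][j] + 1L):max(cuts[[2]][j + 1L], cuts[[2]][j] + 1L)
        zs <- (cuts[[3]][k] + 1L):max(cuts[[3]][k + 1L], cuts[[3]][k] + 1L)
        out[i, j, k] <- mean(arr[xs, ys, zs])
      }
    }
  }
  out
}

# Pooled, rescaled input representation of a patch pair.
encoder_input <- function(patch, pool = 5L) {
  x <- c(pool_patch(patch$insp, pool), pool_patch(patch$exp, pool)) / 1000
  x
}

# Stochastic augmentation: random axis flips, random crop (>= 70% extent,
# re-pooled, i.e. crop-resize), and additive HU jitter.
augment_patch <- function(patch, hu_jitter_sd = 20) {
  flip <- stats::runif(3) < 0.5
  crop_frac <- stats::runif(3, 0.7, 1)
  a <- patch$insp
  b <- patch$exp
  d <- dim(a)
  keep <- pmax(2L, as.integer(round(d * crop_frac)))
  start <- vapply(seq_len(3), function(ax) {
    sample.int(d[ax] - keep[ax] + 1L, 1L)
  }, integer(1))
  ix <- start[1]:(start[1] + keep[1] - 1L)
  iy <- start[2]:(start[2] + keep[2] - 1L)
  iz <- start[3]:(start[3] + keep[3] - 1L)
  a <- a[ix, iy, iz, drop = FALSE]
  b <- b[ix, iy, iz, drop = FALSE]
  if (flip[1]) { a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]; b <- b[rev(seq_len(dim(b)[1])), , , drop = FALSE] }
  if (flip[2]) { a <- a[, rev(seq_len(dim(a)[2])), , drop = FALSE]; b <- b[, rev(seq_len(dim(b)[2])), , drop = FALSE] }
  if (flip[3]) { a <- a[, , rev(seq_len(dim(a)[3])), drop = FALSE]; b <- b[, , rev(seq_len(dim(b)[3])), drop = FALSE] }
  a <- a + stats::rnorm(1, 0, hu_jitter_sd)
  b <- b + stats::rnorm(1, 0, hu_jitter_sd)
  list(insp = a, exp = b, mask = NULL)
}

l2_normalize_rows <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  nrm[nrm < 1e-12] <- 1e-12
  Z / nrm
}

# InfoNCE (NT-Xent) loss and analytic gradient w.r.t. the embedding rows.
# U: 2n x d L2-normalized embeddings; row i's positive is pos[i].
info_nce <- function(U, pos, temperature) {
  m <- nrow(U)
  S <- tcrossprod(U) / temperature
  diag(S) <- -Inf
  Smax <- apply(S, 1, max)
  E <- exp(S - Smax)
  rs <- rowSums(E)
  P <- E / rs
  pos_idx <- cbind(seq_len(m), pos)
  loss <- mean(-S[pos_idx] + log(rs) + Smax)
  # dL/dU accumulated over both the "anchor" role and appearances as a
  # candidate in other rows' softmax.
  G <- (P %*% U)              # sum_j P_ij u_j   (anchor role)
  G <- G + crossprod(P, U)    # sum_i P_ij u_i   (candidate role)
  Upos <- U[pos, , drop = FALSE]
  G <- G - 2 * Upos           # positive appears once per role
  list(loss = loss, grad = G / (temperature * m))
}

#' Train a small contrastive patch encoder
#'
#' Trains a linear encoder on pooled patch-pair intensities with an
#' InfoNCE objective: two stochastic augmentations (axis flips, random
#' crop-resize, HU jitter) of the same patch form a positive pair, all
#' other views in the batch act as negatives, and gradient descent on the
#' full batch maximizes agreement between positives on the unit sphere.
#' This is a lightweight, fully deterministic (given `seed`) featurizer
#' alternative; it makes no claim of matching a full-scale self-supervised
#' 3D encoder.
#'
#' @param patches List of patch records (from [extract_patch_pairs()]).
#' @param epochs Number of full-batch gradient steps (>= 0).
#' @param d_out Embedding dimension (default 32).
#' @param pool Pooling grid side for the input representation (default 5).
#' @param temperature InfoNCE temperature (default 0.2).
#' @param learning_rate Gradient-descent step size (default 1).
#' @param hu_jitter_sd HU jitter augmentation SD (default 20).
#' @param seed Integer seed controlling initialization and augmentations.
#' @return A `phenomap_encoder` with the weight matrix and a `loss_trace`.
#' @export
train_contrastive_encoder <- function(patches, epochs = 30L, d_out = 32L,
                                      pool = 5L, temperature = 0.2,
                                      learning_rate = 1, hu_jitter_sd = 20,
                                      seed = 1L) {
  if (length(patches) < 2L) stop_validation("need at least 2 patches")
  if (epochs < 0L) stop_validation("epochs must be >= 0")
  d_in <- 2L * pool^3
  # Standardize input dimensions over the training set: pooled HU patterns
  # share a large common component that would otherwise collapse all
  # embeddings onto one direction.
  X0 <- t(vapply(patches, function(p) encoder_input(p, pool), numeric(d_in)))
  in_center <- colMeans(X0)
  in_scale <- pmax(apply(X0, 2, stats::sd), 1e-6)
  with_seed(seed, {
    W <- matrix(stats::rnorm(d_out * d_in, sd = 1 / sqrt(d_in)), d_out, d_in)
    loss_trace <- numeric(0)
    n <- length(patches)
    pos <- c(seq_len(n) + n, seq_len(n))
    for (ep in seq_len(epochs)) {
      X <- t(vapply(c(patches, patches), function(p) {
        encoder_input(augment_patch(p, hu_jitter_sd), pool)
      }, numeric(d_in)))
      X <- sweep(sweep(X, 2, in_center), 2, in_scale, "/")
      Z <- X %*% t(W)
      U <- l2_normalize_rows(Z)
      res <- info_nce(U, pos, temperature)
      loss_trace <- c(loss_trace, res$loss)
      # backprop through row normalization: dz = (g - (g.u) u) / ||z||
      nrm <- sqrt(rowSums(Z^2))
      nrm[nrm < 1e-12] <- 1e-12
      Gu <- res$grad
      dZ <- (Gu - U * rowSums(Gu * U)) / nrm
      dW <- t(dZ) %*% X  # (d_out x d_in), matches W
      W <- W - learning_rate * dW
    }
    structure(
      list(W = W, pool = pool, d_out = d_out, temperature = temperature,
           in_center = in_center, in_scale = in_scale,
           epochs = epochs, seed = seed, loss_trace = loss_trace,
           id = sprintf("contrastive_linear_d%d_seed%d", d_out, seed)),
      class = "phenomap_encoder"
    )
  })
}

#' Encode one patch with a trained contrastive encoder
#' @param encoder A `phenomap_encoder`.
#' @param patch A patch record.
#' @return Numeric vector of length `encoder$d_out`.
#' @export
encode_patch <- function(encoder, patch) {
  x <- encoder_input(patch, encoder$pool)
  x <- (x - encoder$in_center) / encoder$in_scale
  as.numeric(encoder$W %*% x)
}

#' @export
print.phenomap_encoder <- function(x, ...) {
  cat(sprintf("<contrastive encoder> %d -> %d dims, %d epochs, final loss %.4f\n",
              ncol(x$W), x$d_out, x$epochs,
              if (length(x$loss_trace)) x$loss_trace[length(x$loss_trace)] else NA))
  invisible(x)
}
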