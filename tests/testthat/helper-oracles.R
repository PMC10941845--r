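# Independent brute-force oracles shared across test files. Each is a
# deliberately naive re-derivation of the quantity it checks, written
# without reference to the package implementation.

oracle_jt_pairs <- function(groups) {
  jt <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      for (x in groups[[i]]) {
        for (y in groups[[j]]) {
          jt <- jt + (x < y) + 0.5 * (x == y)
        }
      }
    }
  }
  jt
}

oracle_silhouette_score <- function(X, labels) {
  D <- as.matrix(dist(X))
  mean(vapply(seq_len(nrow(X)), function(i) {
    same <- which(labels == labels[i] & seq_along(labels) != i)
    if (!length(same)) return(0)
    a <- mean(D[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

oracle_ch_score <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  gm <- colMeans(X)
  b <- sum(vapply(unique(labels), function(g) {
    m <- colMeans(X[labels == g, , drop = FALSE])
    sum(labels == g) * sum((m - gm)^2)
  }, numeric(1)))
  w <- sum(vapply(unique(labels), function(g) {
    Xi <- X[labels == g, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi))^2)
  }, numeric(1)))
  (b / (k - 1)) / (w / (n - k))
}

oracle_db_score <- function(X, labels) {
  gs <- sort(unique(labels)); k <- length(gs)
  cent <- t(sapply(gs, function(g) colMeans(X[labels == g, , drop = FALSE])))
  sc <- sapply(seq_len(k), function(i) {
    mean(sqrt(rowSums(sweep(X[labels == gs[i], , drop = FALSE], 2, cent[i, ])^2)))
  })
  mean(sapply(seq_len(k), function(i) {
    max(sapply(setdiff(seq_len(k), i), function(j) {
      (sc[i] + sc[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }))
  }))
}

make_blobs <- function(k = 4, n_per = 50, d = 5, sep = 10, seed = 21) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(k * d), k, d) * sep
    X <- do.call(rbind, lapply(seq_len(k), function(j) {
      sweep(matrix(rnorm(n_per * d), n_per, d), 2, centers[j, ], `+`)
    }))
    list(X = X, labels = rep(seq_len(k), each = n_per))
  })
}
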