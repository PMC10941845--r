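test_that("parallel analysis recovers a planted rank-3 structure", {
  withr::with_seed(5, {
    n <- 1000; d <- 20
    L <- matrix(rnorm(d * 3), d, 3) * 2
    X <- matrix(rnorm(n * 3), n, 3) %*% t(L) + matrix(rnorm(n * d, sd = 0.5), n, d)
  })
  pca <- fit_pca_with_retention(X, seed = 9)
  expect_equal(pca$n_horn, 3L)
  expect_equal(pca$n_retained, 3L)
  expect_true(all(diff(pca$eigenvalues) <= 0))
  expect_true(all(pca$eigenvalues >= 0))
})

test_that("parallel analysis retains at most one component on pure noise", {
  withr::with_seed(6, X <- matrix(rnorm(500 * 15), 500, 15))
  pca <- fit_pca_with_retention(X, seed = 10)
  expect_lte(pca$n_horn, 1L)
})

test_that("the Kaiser count equals the number of correlation eigenvalues above 1", {
  # two three-column blocks: correlation eigenvalues ~ (2.7, 2.7, rest < 1)
  withr::with_seed(7, {
    z1 <- rnorm(300); z2 <- rnorm(300)
    X <- cbind(z1 + rnorm(300, sd = 0.3), z1 + rnorm(300, sd = 0.3),
               z1 + rnorm(300, sd = 0.3),
               z2 + rnorm(300, sd = 0.3), z2 + rnorm(300, sd = 0.3),
               z2 + rnorm(300, sd = 0.3))
  })
  pca <- fit_pca_with_retention(X, seed = 2)
  expect_equal(pca$n_kaiser, sum(eigen(cor(X), only.values = TRUE)$values > 1))
  expect_equal(pca$n_kaiser, 2L)
})

test_that("quality metrics match brute-force formulas", {
  bd <- make_blobs(k = 3, n_per = 40, d = 4, sep = 3)
  X <- bd$X; lab <- bd$labels
  expect_equal(cluster_silhouette(X, lab), oracle_silhouette_score(X, lab),
               tolerance = 1e-9)
  expect_equal(cluster_calinski_harabasz(X, lab), oracle_ch_score(X, lab),
               tolerance = 1e-9)
  expect_equal(cluster_davies_bouldin(X, lab), oracle_db_score(X, lab),
               tolerance = 1e-9)
  skip_if_not_installed("cluster")
  sil_pkg <- mean(cluster::silhouette(lab, dist(X))[, "sil_width"])
  expect_equal(cluster_silhouette(X, lab), sil_pkg, tolerance = 1e-9)
})

test_that("model selection finds four planted blobs with matching labels", {
  bd <- make_blobs(k = 4, n_per = 50, d = 5, sep = 10)
  cl <- cluster_latent(bd$X, k_range = 2:6, seed = 3)
  expect_equal(cl$k, 4L)
  expect_gte(rand_index_adjusted(cl$assignments, bd$labels), 0.99)
  # determinism
  cl2 <- cluster_latent(bd$X, k_range = 2:6, seed = 3)
  expect_identical(cl$assignments, cl2$assignments)
})

test_that("a single blob is flagged as weak cluster structure", {
  withr::with_seed(8, X <- matrix(rnorm(300 * 4), 300, 4))
  cl <- cluster_latent(X, methods = "minibatch_kmeans", k_range = 2:4, seed = 4)
  expect_lt(cl$quality[["silhouette"]], 0.3)
  expect_true(cl$no_structure)
})

test_that("subject cluster volumes are proper fractions", {
  fix <- mid_cohort()
  withr::with_seed(3, {
    assignments <- sample.int(4, nrow(fix$features$meta), replace = TRUE)
  })
  vols <- cluster_subject_volumes(assignments, fix$features$meta, k = 4)
  frac <- as.matrix(vols[, -1])
  expect_equal(unname(rowSums(frac)), rep(1, nrow(frac)))
  # direct count check on the first subject
  sid <- vols$subject_id[1]
  a <- assignments[fix$features$meta$subject_id == sid]
  expect_equal(unname(frac[1, ]), unname(tabulate(a, 4) / length(a)))
  # all-in-one-cluster subject
  meta1 <- data.frame(subject_id = "only")
  v1 <- cluster_subject_volumes(2L, meta1, k = 4)
  expect_equal(unname(as.matrix(v1[, -1])[1, ]), c(0, 1, 0, 0))
})

test_that("cluster maps paint nearest-patch labels over the lung", {
  mask <- array(TRUE, dim = c(20, 10, 10))
  grid <- plan_patches(mask, patch_size = 10, overlap_fraction = 0,
                       min_lung_fraction = 0)
  m <- render_cluster_map(c(1L, 2L), grid, mask)
  expect_true(all(m[1:10, , ] == 1L))
  expect_true(all(m[11:20, , ] == 2L))
  # single patch paints its whole extent
  g1 <- plan_patches(array(TRUE, dim = c(10, 10, 10)), patch_size = 10,
                     min_lung_fraction = 0)
  m1 <- render_cluster_map(3L, g1, array(TRUE, dim = c(10, 10, 10)))
  expect_true(all(m1 == 3L))
  # non-lung stays background
  mask2 <- mask; mask2[1:3, , ] <- FALSE
  m2 <- render_cluster_map(c(1L, 2L), grid, mask2)
  expect_true(all(m2[1:3, , ] == 0L))
})

test_that("t-SNE separates classes and transforms new points deterministically", {
  withr::with_seed(17, {
    A <- matrix(rnorm(60 * 8), 60, 8)
    B <- matrix(rnorm(60 * 8, mean = 5), 60, 8)
    newA <- matrix(rnorm(10 * 8), 10, 8)
    newB <- matrix(rnorm(10 * 8, mean = 5), 10, 8)
  })
  em <- tsne_embed(rbind(A, B), rbind(newA, newB), seed = 6, n_iter = 300)
  expect_equal(dim(em$fit), c(120L, 2L))
  expect_equal(dim(em$transform), c(20L, 2L))
  lab <- rep(1:2, each = 60)
  intra <- mean(dist(em$fit[lab == 1, ]))
  inter <- mean(as.matrix(dist(em$fit))[lab == 1, lab == 2])
  expect_gt(inter, intra)
  # transformed points land near their own class
  tl <- rep(1:2, each = 10)
  d_to_1 <- colMeans(as.matrix(dist(rbind(em$fit[lab == 1, ], em$transform)))[1:60, 61:80])
  expect_lt(mean(d_to_1[tl == 1]), mean(d_to_1[tl == 2]))
  em2 <- tsne_embed(rbind(A, B), rbind(newA, newB), seed = 6, n_iter = 300)
  expect_identical(em$fit, em2$fit)
  expect_error(tsne_embed(A[1:20, ]), class = "phenomap_validation_error")
})
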