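# Independent mixture log-density oracle (solve/det based, no Cholesky).
oracle_mixture_nll <- function(density, X) {
  Z <- if (!is.null(density$whitener)) {
    sweep(sweep(X, 2, density$whitener$center) %*% density$whitener$rotation,
          2, density$whitener$sdev, "/")
  } else X
  -log(vapply(seq_len(nrow(Z)), function(i) {
    sum(vapply(seq_len(density$n_components), function(g) {
      S <- density$covariances[[g]]
      d <- length(density$means[g, ])
      diff <- Z[i, ] - density$means[g, ]
      density$weights[g] * exp(-0.5 * drop(t(diff) %*% solve(S) %*% diff)) /
        sqrt((2 * pi)^d * det(S))
    }, numeric(1)))
  }, numeric(1)))
}

fake_features <- function(meta, mat = NULL) {
  if (is.null(mat)) mat <- matrix(rnorm(nrow(meta) * 4), nrow(meta), 4)
  structure(list(matrix = mat, meta = meta, featurizer_id = "test"),
            class = "phenomap_features")
}

test_that("reference patches come from healthy subjects with <1% emphysema", {
  meta <- data.frame(
    subject_id = c("a", "a", "b", "c"),
    stage = c("GOLD0", "GOLD0", "GOLD3", "control"),
    emph_pct = c(0, 2, 0, 0.5)
  )
  sel <- select_reference_patches(fake_features(meta))
  expect_equal(sel, c(TRUE, FALSE, FALSE, TRUE))
  meta_bad <- data.frame(subject_id = "x", stage = "GOLD4", emph_pct = 50)
  expect_error(select_reference_patches(fake_features(meta_bad)),
               class = "phenomap_config_error")
})

test_that("a single-Gaussian reference recovers its generating moments", {
  withr::with_seed(12, {
    X <- matrix(rnorm(5000 * 5), 5000, 5)
  })
  dens <- fit_reference_density(X, family = "gaussian", whiten = FALSE)
  expect_true(all(abs(dens$means[1, ]) < 0.05))
  expect_true(all(abs(diag(dens$covariances[[1]]) - 1) < 0.1))
  # NLL at the fitted mean equals the closed form 0.5 log((2 pi)^d det S)
  at_mean <- score_patches(dens, matrix(dens$means[1, ], 1))
  expect_equal(at_mean,
               0.5 * log((2 * pi)^5 * det(dens$covariances[[1]])),
               tolerance = 1e-10)
})

test_that("BIC selects two components for two well-separated blobs", {
  withr::with_seed(13, {
    X <- rbind(matrix(rnorm(400 * 5), 400, 5),
               matrix(rnorm(400 * 5, mean = 8), 400, 5))
  })
  dens <- fit_reference_density(X, family = "gaussian_mixture", k_range = 1:4,
                                whiten = FALSE, seed = 3)
  expect_equal(dens$n_components, 2L)
  expect_equal(sum(dens$weights), 1, tolerance = 1e-12)
})

test_that("scores match an independent log-density evaluation", {
  withr::with_seed(14, {
    X <- rbind(matrix(rnorm(300 * 6), 300, 6),
               matrix(rnorm(300 * 6, mean = 4), 300, 6))
    Y <- matrix(rnorm(50 * 6, mean = 2), 50, 6)
  })
  dens <- fit_reference_density(X, family = "gaussian_mixture", k_range = 2,
                                whiten = TRUE, whiten_dims = 6, seed = 5)
  expect_equal(score_patches(dens, Y), oracle_mixture_nll(dens, Y),
               tolerance = 1e-8)
})

test_that("scores grow monotonically with Mahalanobis distance", {
  withr::with_seed(15, X <- matrix(rnorm(800 * 3), 800, 3))
  dens <- fit_reference_density(X, family = "gaussian", whiten = FALSE)
  pts <- outer(seq(0, 5, by = 0.5), c(1, 1, 1))
  sc <- score_patches(dens, pts)
  expect_true(all(diff(sc) > 0))
})

test_that("patient aggregation follows the chosen rule", {
  expect_equal(aggregate_patient_score(3.5), 3.5)
  expect_equal(aggregate_patient_score(rep(2.2, 10)), 2.2)
  x <- c(1, 4, 10)
  expect_equal(aggregate_patient_score(x), mean(x))
  expect_equal(aggregate_patient_score(x, "median"), 4)
  expect_equal(aggregate_patient_score(x, "max"), 10)
  expect_error(aggregate_patient_score(numeric(0)),
               class = "phenomap_validation_error")
})

test_that("anomaly maps normalize to the 5th/95th percentile window", {
  mask <- array(TRUE, dim = c(20, 20, 20))
  grid <- plan_patches(mask, patch_size = 10, overlap_fraction = 0,
                       min_lung_fraction = 0)
  expect_equal(nrow(grid$origins), 8L)
  scores <- c(1, 2, 3, 4, 5, 6, 7, 100)
  bounds <- c(2, 6)  # play the cohort p5/p95 roles
  m <- render_anomaly_map(scores, grid, mask, bounds)
  block <- function(i) m[grid$origins[i, 1] + 5, grid$origins[i, 2] + 5,
                         grid$origins[i, 3] + 5]
  expect_equal(block(2), 0)          # at p5 -> 0
  expect_equal(block(6), 1)          # at p95 -> 1
  expect_equal(block(8), 1)          # above p95 clipped
  expect_equal(block(1), 0)          # below p5 clipped
  expect_equal(block(4), (4 - 2) / 4)
  expect_true(all(m >= 0 & m <= 1))

  # voxel covered by two patches averages their raw scores
  grid2 <- plan_patches(array(TRUE, dim = c(15, 10, 10)), patch_size = 10,
                        overlap_fraction = 0.5, min_lung_fraction = 0)
  m2 <- render_anomaly_map(c(0, 4), grid2, array(TRUE, dim = c(15, 10, 10)),
                           bounds = c(0, 4))
  expect_equal(m2[8, 5, 5], 0.5)  # overlap zone: (0 + 4)/2 scaled to [0,1]

  expect_warning(m3 <- render_anomaly_map(scores, grid, mask, c(3, 3)))
  expect_true(all(m3 == 0))
})

test_that("anomaly stage ranks diseased subjects above healthy ones", {
  fix <- mid_cohort()
  pt <- merge(fix$anomaly$patient,
              fix$cohort$truth[, c("subject_id", "emph_fraction", "fsad_fraction")],
              by = "subject_id")
  rho <- cor(pt$patient_score, pt$emph_fraction + pt$fsad_fraction,
             method = "spearman")
  expect_gte(rho, 0.8)
  # held-out reference-like patches score below lesion-rich patches
  ref_scores <- fix$anomaly$patch_scores[fix$anomaly$reference_mask]
  rich <- fix$features$meta$emph_pct > 20
  expect_lt(median(ref_scores), median(fix$anomaly$patch_scores[rich]))
})
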