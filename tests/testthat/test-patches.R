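test_that("patch planning follows the stride rule with edge clamping", {
  all_lung <- function(d) array(TRUE, dim = d)

  g1 <- plan_patches(all_lung(c(50, 50, 50)), patch_size = 50)
  expect_equal(nrow(g1$origins), 1L)
  expect_equal(unname(g1$origins[1, ]), c(0L, 0L, 0L))
  expect_equal(g1$coverage, 1)

  # 90^3 with stride 40: origins {0, 40} per axis -> 8 patches
  g2 <- plan_patches(all_lung(c(90, 90, 90)), patch_size = 50, overlap_fraction = 0.2)
  expect_equal(g2$stride, 40L)
  expect_equal(nrow(g2$origins), 8L)
  expect_setequal(unique(g2$origins[, 1]), c(0L, 40L))

  # non-multiple extent: final origin clamped to end at the edge
  g3 <- plan_patches(all_lung(c(64, 64, 64)), patch_size = 50)
  expect_setequal(unique(g3$origins[, 1]), c(0L, 14L))

  # short axis shrinks the patch when clamping is on, errors when off
  g4 <- plan_patches(all_lung(c(64, 64, 40)), patch_size = 50)
  expect_equal(g4$extent, c(50L, 50L, 40L))
  expect_error(plan_patches(all_lung(c(64, 64, 40)), patch_size = 50, clamp = FALSE),
               class = "phenomap_dimension_error")
})

test_that("low-lung patches are dropped and coverage reflects kept patches", {
  mask <- array(FALSE, dim = c(90, 90, 90))
  mask[1:45, , ] <- TRUE  # lung fills only the low-x half
  g <- plan_patches(mask, patch_size = 50, min_lung_fraction = 0.5)
  expect_true(all(g$origins[, 1] == 0L))
  expect_true(all(g$lung_fraction >= 0.5))
  expect_gt(g$coverage, 0.7)
})

test_that("patch extraction crops exactly and tiles reassemble the volume", {
  s <- tiny_cohort()$subjects[[3]]$study

  # identity crop: one patch spanning the whole (clamped) volume
  g1 <- plan_patches(s$lung_mask, patch_size = 64, min_lung_fraction = 0)
  p1 <- extract_patch_pairs(s, g1)
  expect_length(p1, 1L)
  expect_identical(p1[[1]]$insp, s$insp)

  # overlapping patches agree bit-exactly on shared voxels
  g <- plan_patches(s$lung_mask, min_lung_fraction = 0)
  pp <- extract_patch_pairs(s, g)
  o1 <- g$origins[1, ]; o2 <- g$origins[2, ]   # differ along x only
  shared_1 <- pp[[1]]$insp[(o2[1] + 1):g$extent[1], , ]
  shared_2 <- pp[[2]]$insp[1:(g$extent[1] - o2[1]), , ]
  expect_identical(shared_1, shared_2)

  # non-overlapping tiling (stride = size) reassembles the original grid
  g0 <- plan_patches(s$lung_mask, patch_size = 32, overlap_fraction = 0,
                     min_lung_fraction = 0)
  tiles <- extract_patch_pairs(s, g0)
  rebuilt <- array(NA_real_, dim = dim(s$insp))
  for (i in seq_along(tiles)) {
    o <- g0$origins[i, ]
    rebuilt[(o[1] + 1):(o[1] + g0$extent[1]),
            (o[2] + 1):(o[2] + g0$extent[2]),
            (o[3] + 1):(o[3] + g0$extent[3])] <- tiles[[i]]$insp
  }
  expect_identical(rebuilt, s$insp)
})

test_that("default patch grids cover more than 70% of the lung", {
  for (s in tiny_cohort()$subjects[c(1, 6, 12)]) {
    g <- plan_patches(s$study$lung_mask)
    expect_gt(g$coverage, 0.7)
    # bookkeeping: every kept patch lies inside the grid
    expect_true(all(g$origins >= 0))
    expect_true(all(sweep(g$origins, 2, g$extent, `+`) <=
                      matrix(g$grid_shape, nrow(g$origins), 3, byrow = TRUE)))
  }
})

test_that("histogram features are deterministic and class-discriminative", {
  pure <- pure_class_patches()

  # constant-HU patch: all mass in one bin per phase
  const_patch <- list(insp = array(-870, c(8, 8, 8)), exp = array(-740, c(8, 8, 8)),
                      mask = array(TRUE, c(8, 8, 8)))
  f <- featurize_histogram(const_patch, n_bins = 32, d = 80)
  expect_equal(max(f[1:32]), 1)
  expect_equal(sum(f[1:32] > 0), 1L)
  expect_equal(sum(f[33:64] > 0), 1L)

  # identical patches give identical vectors
  expect_identical(featurize_histogram(pure$normal[[1]]),
                   featurize_histogram(pure$normal[[1]]))

  # emphysema and normal patches are farther apart than within-class pairs
  fn <- t(vapply(pure$normal[1:10], featurize_histogram, numeric(512)))
  fe <- t(vapply(pure$emph[1:10], featurize_histogram, numeric(512)))
  d_within <- mean(dist(fn)) + mean(dist(fe))
  d_between <- mean(as.matrix(dist(rbind(fn, fe)))[1:10, 11:20])
  expect_gt(d_between, d_within / 2)

  expect_error(featurize_histogram(list(insp = array(0, c(2, 2, 2)),
                                        exp = array(0, c(2, 2, 2)),
                                        mask = array(FALSE, c(2, 2, 2)))),
               class = "phenomap_validation_error")
})

test_that("embed_cohort stacks features with aligned metadata", {
  feats <- mid_cohort()$features
  expect_equal(nrow(feats$matrix), nrow(feats$meta))
  expect_true(all(is.finite(feats$matrix)))
  expect_equal(feats$featurizer_id, "histogram")
  # per-subject patch counts match the planned grids
  counts <- table(feats$meta$subject_id)
  for (sid in names(counts)[1:5]) {
    expect_equal(unname(counts[[sid]]), nrow(feats$grids[[sid]]$origins))
  }
  # determinism
  coh_small <- tiny_cohort()
  f1 <- embed_cohort(coh_small, d = 96L)
  f2 <- embed_cohort(coh_small, d = 96L)
  expect_identical(f1$matrix, f2$matrix)
})
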