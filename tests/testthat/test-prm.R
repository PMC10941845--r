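# Reference per-voxel classifier: a direct transcription of the PRM HU
# boxes, evaluated one voxel at a time, independent of the vectorized path.
prm_reference_loop <- function(insp, exp) {
  vapply(seq_along(insp), function(i) {
    a <- insp[i]; b <- exp[i]
    if (a >= -1000 && a <= -950 && b >= -1000 && b < -856) 3L
    else if (a > -950 && a <= -810 && b >= -1000 && b < -856) 2L
    else if (a > -950 && a <= -810 && b >= -856 && b <= -500) 1L
    else 4L
  }, integer(1))
}

test_that("canonical HU pairs map to their PRM classes", {
  codes <- classify_voxels(
    insp_hu = c(-960, -900, -900, -300),
    exp_hu  = c(-900, -950, -700, -200)
  )
  expect_equal(prm_class_names(codes), c("Emph", "fSAD", "Normal", "Excluded"))
})

test_that("shared HU boundaries follow the declared closure convention", {
  # -950 on inspiration belongs to Emph; just above it is the fSAD band
  expect_equal(prm_class_names(classify_voxels(-950, -900)), "Emph")
  expect_equal(prm_class_names(classify_voxels(-949.999, -900)), "fSAD")
  # -856 on expiration belongs to Normal; just below is air trapping
  expect_equal(prm_class_names(classify_voxels(-900, -856)), "Normal")
  expect_equal(prm_class_names(classify_voxels(-900, -856.001)), "fSAD")
  # interval ends
  expect_equal(prm_class_names(classify_voxels(-1000, -1000)), "Emph")
  expect_equal(prm_class_names(classify_voxels(-810, -500)), "Normal")
  expect_equal(prm_class_names(classify_voxels(-809.999, -700)), "Excluded")
})

test_that("vectorized classification matches the per-voxel reference loop", {
  set.seed(42)
  n <- 50000
  insp <- runif(n, -1100, 0)
  exp <- runif(n, -1100, 0)
  expect_identical(classify_voxels(insp, exp), prm_reference_loop(insp, exp))
  # every voxel gets exactly one label
  expect_true(all(classify_voxels(insp, exp) %in% 1:4))
})

test_that("classify_voxels validates its inputs", {
  expect_error(classify_voxels(c(-900, NA), c(-700, -700)),
               class = "phenomap_validation_error")
  expect_error(classify_voxels(-900, c(-700, -700)),
               class = "phenomap_validation_error")
})

test_that("compute_prm partitions the lung and sums percentages to 100", {
  s <- tiny_cohort()$subjects[[8]]
  p <- compute_prm(s$study)
  expect_equal(p$pct_normal + p$pct_fsad + p$pct_emph, 100, tolerance = 1e-6)
  expect_true(all(p$labelmap[!s$study$lung_mask] == 0L))
  expect_true(all(p$labelmap[s$study$lung_mask] %in% 1:4))
  # per-class counts equal a brute-force count over the lung
  lung <- which(s$study$lung_mask)
  ref <- prm_reference_loop(s$study$insp[lung], s$study$exp_registered[lung])
  for (cls in 1:4) {
    expect_equal(sum(p$labelmap[lung] == cls), sum(ref == cls))
  }
})

test_that("an all-normal lung is classified 100% normal", {
  cfg <- cohort_config(
    n_per_stage = 1, seed = 5, grid_shape = c(24L, 24L, 20L),
    stage_burden_means = list(emph = rep(0, 6), fsad = rep(0, 6))
  )
  s <- generate_subject("control", cfg, seed = 2)
  p <- compute_prm(s$study)
  expect_equal(p$pct_normal, 100)
  expect_equal(p$pct_emph, 0)
  expect_equal(p$pct_excluded, 0)
})

test_that("ground-truth lesion voxels are recovered by their PRM class", {
  s <- mid_cohort()$cohort$subjects[[110]]  # a GOLD4 subject
  p <- compute_prm(s$study)
  truth <- s$truth$tissue_labelmap
  for (cls in 1:3) {
    vox <- which(truth == cls)
    expect_gte(mean(p$labelmap[vox] == cls), 0.95)
  }
})

test_that("compute_prm rejects malformed studies", {
  s <- tiny_cohort()$subjects[[1]]$study
  bad <- s
  bad$exp_registered <- bad$exp_registered[, , 1:10]
  expect_error(compute_prm(bad), class = "phenomap_dimension_error")
  bad2 <- s
  bad2$lung_mask <- array(FALSE, dim = dim(s$insp))
  expect_error(compute_prm(bad2), class = "phenomap_validation_error")
})

test_that("laa_percent counts voxels below threshold", {
  set.seed(7)
  hu <- array(runif(4000, -1000, 0), dim = c(20, 20, 10))
  mask <- array(TRUE, dim = dim(hu))
  # brute force
  expect_equal(laa_percent(hu, mask, -500), 100 * sum(hu < -500) / 4000)
  expect_equal(laa_percent(hu, mask, -1025), 0)
  # exactly 30% below the threshold
  v <- array(c(rep(-980, 30), rep(-200, 70)), dim = c(10, 10, 1))
  expect_equal(laa_percent(v, array(TRUE, dim(v)), -950), 30)
  expect_error(laa_percent(hu, array(FALSE, dim(hu)), -950),
               class = "phenomap_validation_error")
})

test_that("cohort PRM means rise strictly with severity stage", {
  prm <- calib_cohort()$prm
  stage <- factor(prm$stage, stage_levels())
  expect_true(all(diff(tapply(prm$pct_emph, stage, mean)) > 0))
  expect_true(all(diff(tapply(prm$pct_fsad, stage, mean)) > 0))
})
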