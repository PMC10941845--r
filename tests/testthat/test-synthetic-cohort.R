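test_that("subject generation is deterministic and honours burden targets", {
  cfg <- cohort_config(n_per_stage = 2, seed = 1)
  a <- generate_subject("GOLD3", cfg, seed = 99)
  b <- generate_subject("GOLD3", cfg, seed = 99)
  expect_identical(a$study$insp, b$study$insp)
  expect_identical(a$study$exp_registered, b$study$exp_registered)
  expect_identical(a$truth$tissue_labelmap, b$truth$tissue_labelmap)
  expect_identical(a$clinical, b$clinical)

  # the labelled fractions equal labelmap counts over lung voxels
  n_lung <- sum(a$study$lung_mask)
  expect_equal(a$truth$emph_fraction,
               sum(a$truth$tissue_labelmap == 3L) / n_lung)
  expect_equal(a$truth$fsad_fraction,
               sum(a$truth$tissue_labelmap == 2L) / n_lung)
  expect_lte(a$truth$emph_fraction + a$truth$fsad_fraction, 1)
})

test_that("zero burden means give an all-normal lung", {
  cfg <- cohort_config(
    n_per_stage = 1, seed = 2,
    stage_burden_means = list(emph = rep(0, 6), fsad = rep(0, 6))
  )
  s <- generate_subject("GOLD4", cfg, seed = 5)
  lung_labels <- s$truth$tissue_labelmap[s$study$lung_mask]
  expect_true(all(lung_labels == 1L))
  expect_identical(s$truth$emph_fraction, 0)
})

test_that("control subjects carry a near-zero emphysema burden", {
  cfg <- cohort_config(n_per_stage = 1, seed = 3)
  fr <- vapply(1:8, function(i) {
    generate_subject("control", cfg, seed = i)$truth$emph_fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.003), 0.004)
})

test_that("cohorts have the right composition and reproducible site layout", {
  coh <- tiny_cohort()
  expect_length(coh$subjects, 12L)
  expect_equal(as.integer(table(coh$clinical$stage)), rep(2L, 6))
  expect_true(all(coh$clinical$site_id %in% seq_len(coh$config$n_sites)))
  # round-robin: consecutive subjects cycle through the sites
  expect_equal(coh$clinical$site_id[1:4], 1:4)

  coh2 <- generate_cohort(cohort_config(n_per_stage = 2, seed = 101))
  expect_equal(coh$clinical, coh2$clinical)
})

test_that("clinical records satisfy physiological invariants", {
  cl <- mid_cohort()$cohort$clinical
  expect_true(all(cl$TLC >= cl$FRC))
  expect_true(all(cl$FRC > 0))
  expect_equal(cl$FRC_TLC, cl$FRC / cl$TLC, tolerance = 1e-9)
  expect_true(all(cl$BODE >= 0 & cl$BODE <= 10))
  expect_true(all(cl$SGRQ >= 0 & cl$SGRQ <= 100))
  expect_true(all(cl$FEV1_FVC > 0 & cl$FEV1_FVC < 1))
  expect_true(all(cl$smoking_duration[cl$stage == "control"] == 0))
  expect_true(all(cl$smoking_status[cl$stage != "control"] %in% 1:2))
})

test_that("lesion burden is linked to lung function with the configured sign", {
  dat <- merge(mid_cohort()$cohort$truth, mid_cohort()$cohort$clinical,
               by = c("subject_id", "stage"))
  r <- cor(dat$emph_fraction, dat$FEV1pp)
  expect_lt(r, 0)
  expect_gte(abs(r), 0.5)
})

test_that("cohort mean burdens are monotone over stages", {
  truth <- calib_cohort()$cohort$truth
  means_e <- tapply(truth$emph_fraction, factor(truth$stage, stage_levels()), mean)
  means_f <- tapply(truth$fsad_fraction, factor(truth$stage, stage_levels()), mean)
  expect_true(all(diff(means_e) > 0))
  expect_true(all(diff(means_f) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_stage = 0), class = "phenomap_config_error")
  expect_error(
    cohort_config(stage_burden_means = list(emph = c(0.5, 0.4, rep(0.5, 4)),
                                            fsad = rep(0.1, 6))),
    class = "phenomap_config_error"
  )
  bad_hu <- default_hu_models()
  bad_hu$emph$insp$upper <- -700  # leaks out of the emphysema PRM interval
  expect_error(cohort_config(hu_models = bad_hu), class = "phenomap_config_error")
  expect_error(
    cohort_config(stage_burden_means = list(emph = rep(0.6, 6), fsad = rep(0.5, 6))),
    class = "phenomap_config_error"
  )
  expect_error(generate_subject("GOLD7", cohort_config(), seed = 1),
               class = "phenomap_validation_error")
})

test_that("write_cohort emits the expected files and round-trips exactly", {
  coh <- generate_cohort(cohort_config(n_per_stage = 1, seed = 7,
                                       grid_shape = c(24L, 24L, 20L)))
  # keep only 2 subjects to stay fast
  coh$subjects <- coh$subjects[1:2]
  coh$clinical <- coh$clinical[1:2, ]
  coh$truth <- coh$truth[1:2, ]
  out <- withr::local_tempdir()
  manifest <- write_cohort(coh, out)
  files <- list.files(out)
  expect_length(grep("\\.nii\\.gz$", files), 8L)
  expect_length(grep("\\.csv$", files), 2L)
  expect_true("manifest.json" %in% files)
  expect_equal(manifest$seed, coh$config$seed)

  back <- read_cohort(out)
  s0 <- coh$subjects[[1]]$study
  s1 <- back$subjects[[1]]$study
  expect_equal(max(abs(s0$insp - s1$insp)), 0)
  expect_equal(max(abs(s0$exp_registered - s1$exp_registered)), 0)
  expect_identical(s0$lung_mask, s1$lung_mask)
  expect_equal(coh$subjects[[1]]$truth$tissue_labelmap + 0,
               back$subjects[[1]]$truth$tissue_labelmap + 0)
})
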