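# End-to-end orchestration: simulate -> PRM -> features -> anomaly ->
# cluster -> stats, with one configuration object, plain-file stage
# outputs, and a report generator.

#' Build and validate a pipeline configuration
#'
#' All stage parameters in one validated list. Unknown keys are rejected
#' by name, so typos never silently fall back to defaults. The effective
#' configuration is echoed into the results manifest.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A `phenomap_analysis_config`.
#' @details Defaults: `n_per_stage = 10`, `grid_shape = c(64, 64, 48)`,
#' `seed = 42`, `featurizer = "histogram"`, `feature_dim = 128`,
#' `patch_size = 50`, `overlap_fraction = 0.2`, `min_lung_fraction = 0.2`,
#' `density_family = "gaussian_mixture"`, `density_k_range = 1:4`,
#' `whiten_dims = 16`, `aggregate = "mean"`,
#' `percentiles = c(0.05, 0.95)`, `cluster_k_range = 2:6`,
#' `cluster_methods = c("minibatch_kmeans", "gaussian_mixture")`,
#' `pa_reps = 100`, `pa_percentile = 0.95`, `n_boot = 1000`,
#' `alpha = 0.05`, `holm = TRUE`, `write_volumes = FALSE`.
#' @export
analysis_config <- function(...) {
  defaults <- list(
    n_per_stage = 10L,
    grid_shape = c(64L, 64L, 48L),
    seed = 42L,
    featurizer = "histogram",
    feature_dim = 128L,
    patch_size = 50L,
    overlap_fraction = 0.2,
    min_lung_fraction = 0.2,
    density_family = "gaussian_mixture",
    density_k_range = 1:4,
    whiten_dims = 16L,
    aggregate = "mean",
    percentiles = c(0.05, 0.95),
    cluster_k_range = 2:6,
    cluster_methods = c("minibatch_kmeans", "gaussian_mixture"),
    pa_reps = 100L,
    pa_percentile = 0.95,
    n_boot = 1000L,
    alpha = 0.05,
    holm = TRUE,
    write_volumes = FALSE
  )
  overrides <- list(...)
  if (length(overrides) && is.null(names(overrides))) {
    stop_config("analysis_config() takes named arguments only")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_config(sprintf("unknown configuration key(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  if (!cfg$featurizer %in% c("histogram", "contrastive")) {
    stop_config("featurizer must be 'histogram' or 'contrastive'")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_config("alpha must be in (0, 1)")
  structure(cfg, class = "phenomap_analysis_config")
}

#' Load a pipeline configuration from JSON
#' @param path Path to a JSON file of configuration keys.
#' @return A validated `phenomap_analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}

clinical_variables <- function() {
  c("FEV1pp", "FEV1_FVC", "TLC", "FRC", "FRC_TLC", "BODE", "SGRQ",
    "sixMWT", "smoking_duration")
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> PRM -> features -> anomaly -> cluster -> stats,
#' writing each stage's outputs as plain CSV (and optionally NIfTI
#' volumes) into its own subdirectory of `out_dir`, and a JSON manifest
#' recording the effective configuration and seed. Re-running with the
#' same configuration reproduces identical numeric outputs.
#'
#' @param config A [analysis_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a results list: cohort tables, feature object,
#'   anomaly stage, cluster stage, stats tables, and the manifest path.
#' @export
run_pipeline <- function(config = analysis_config(), out_dir = tempfile("phenomap_")) {
  if (!inherits(config, "phenomap_analysis_config")) {
    stop_config("config must come from analysis_config()")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- function(s) {
    d <- file.path(out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }

  # -- simulate ------------------------------------------------------------
  ccfg <- cohort_config(n_per_stage = config$n_per_stage,
                        grid_shape = config$grid_shape,
                        seed = config$seed)
  cohort <- generate_cohort(ccfg)
  d_sim <- stage_dir("simulate")
  write_stage_csv(cohort$clinical, d_sim, "clinical.csv")
  write_stage_csv(cohort$truth, d_sim, "ground_truth.csv")
  if (isTRUE(config$write_volumes)) write_cohort(cohort, file.path(d_sim, "volumes"))

  # -- prm -----------------------------------------------------------------
  prm <- prm_cohort_table(cohort)
  write_stage_csv(prm, stage_dir("prm"), "prm_volumes.csv")

  # -- features ------------------------------------------------------------
  featurizer <- config$featurizer
  if (identical(featurizer, "contrastive")) {
    ref_subj <- cohort$subjects[[1]]
    grid <- plan_patches(ref_subj$study$lung_mask, config$patch_size,
                         config$overlap_fraction, config$min_lung_fraction)
    train_patches <- unlist(lapply(cohort$subjects[seq_len(min(10, length(cohort$subjects)))],
                                   function(s) extract_patch_pairs(s$study, grid)),
                            recursive = FALSE)
    featurizer <- train_contrastive_encoder(train_patches,
                                            seed = derive_seed(config$seed, 77L))
  }
  features <- embed_cohort(cohort, featurizer = featurizer,
                           patch_size = config$patch_size,
                           overlap_fraction = config$overlap_fraction,
                           min_lung_fraction = config$min_lung_fraction,
                           d = config$feature_dim)
  d_feat <- stage_dir("features")
  write_stage_csv(cbind(features$meta,
                        as.data.frame(features$matrix)), d_feat, "features.csv")

  # -- anomaly -------------------------------------------------------------
  anomaly <- anomaly_stage(features, family = config$density_family,
                           k_range = config$density_k_range,
                           whiten_dims = config$whiten_dims,
                           seed = derive_seed(config$seed, 101L),
                           aggregate = config$aggregate,
                           percentiles = config$percentiles)
  d_anom <- stage_dir("anomaly")
  write_stage_csv(cbind(features$meta[, c("subject_id", "origin_x", "origin_y", "origin_z")],
                        score = anomaly$patch_scores,
                        reference = anomaly$reference_mask),
                  d_anom, "patch_scores.csv")
  write_stage_csv(anomaly$patient, d_anom, "patient_scores.csv")

  # -- cluster -------------------------------------------------------------
  pca <- fit_pca_with_retention(features$matrix, n_pa_reps = config$pa_reps,
                                pa_percentile = config$pa_percentile,
                                seed = derive_seed(config$seed, 202L))
  clusters <- cluster_latent(retained_scores(pca),
                             methods = config$cluster_methods,
                             k_range = config$cluster_k_range,
                             seed = derive_seed(config$seed, 303L))
  volumes <- cluster_subject_volumes(clusters$assignments, features$meta,
                                     k = clusters$k)
  d_clu <- stage_dir("cluster")
  write_stage_csv(data.frame(features$meta[, "subject_id", drop = FALSE],
                             cluster = clusters$assignments),
                  d_clu, "assignments.csv")
  write_stage_csv(clusters$selection_table, d_clu, "selection_table.csv")
  write_stage_csv(volumes, d_clu, "subject_cluster_volumes.csv")

  # -- stats ---------------------------------------------------------------
  stats_out <- cohort_stats_stage(cohort, prm, anomaly, volumes, config)
  d_stats <- stage_dir("stats")
  for (nm in names(stats_out)) {
    write_stage_csv(stats_out[[nm]], d_stats, paste0(nm, ".csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenomap")),
    seed = config$seed,
    config = unclass(config),
    n_retained_pcs = pca$n_retained,
    cluster_method = clusters$method,
    cluster_k = clusters$k,
    stages = c("simulate", "prm", "features", "anomaly", "cluster", "stats")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = out_dir, cohort = cohort, prm = prm,
                 features = features, anomaly = anomaly, pca = pca,
                 clusters = clusters, cluster_volumes = volumes,
                 stats = stats_out, manifest = manifest))
}

# Statistical comparison layer over the assembled per-subject tables.
cohort_stats_stage <- function(cohort, prm, anomaly, volumes, config) {
  subj <- merge(merge(prm, anomaly$patient[, c("subject_id", "patient_score")],
                      by = "subject_id"),
                volumes, by = "subject_id")
  subj <- merge(subj, cohort$clinical, by = c("subject_id", "stage", "site_id"))
  subj$stage <- as.character(subj$stage)
  stage_order <- stage_levels()
  cluster_cols <- grep("^cluster_", names(subj), value = TRUE)
  measures <- c("pct_emph", "pct_fsad", "patient_score", cluster_cols)

  # per-stage summary + JT trend p per measure (Table-2 style analog)
  trend <- do.call(rbind, lapply(measures, function(m) {
    groups <- lapply(stage_order, function(s) subj[[m]][subj$stage == s])
    jt <- jonckheere_terpstra(groups, alternative = "two.sided")
    means <- vapply(groups, mean, numeric(1))
    sds <- vapply(groups, stats::sd, numeric(1))
    row <- data.frame(measure = m, jt_statistic = jt$statistic, jt_z = jt$z,
                      jt_p = jt$p)
    for (i in seq_along(stage_order)) {
      row[[paste0("mean_", stage_order[i])]] <- means[i]
      row[[paste0("sd_", stage_order[i])]] <- sds[i]
    }
    row
  }))

  # correlations of each measure with clinical data (Table-3 style analog)
  cors <- list()
  seed_i <- 0L
  for (m in measures) {
    for (v in clinical_variables()) {
      seed_i <- seed_i + 1L
      ct <- pearson_bootstrap_ci(subj[[m]], subj[[v]],
                                 n_boot = config$n_boot,
                                 seed = derive_seed(config$seed, 400L + seed_i))
      cors[[length(cors) + 1L]] <- data.frame(
        measure = m, variable = v, r = ct$r, ci_low = ct$ci_low,
        ci_high = ct$ci_high, p = ct$p, band = ct$band_label
      )
    }
  }
  cors <- do.call(rbind, cors)
  if (isTRUE(config$holm)) {
    cors$p_holm <- stats::ave(cors$p, cors$measure,
                              FUN = function(p) holm_adjust(p))
  }

  # Zou comparison: anomaly score vs each PRM volume, per clinical variable
  zou <- do.call(rbind, lapply(clinical_variables(), function(v) {
    do.call(rbind, lapply(c("pct_emph", "pct_fsad"), function(m) {
      zd <- zou_correlation_difference(subj[[v]], subj$patient_score, subj[[m]])
      data.frame(variable = v, comparison = sprintf("patient_score vs %s", m),
                 r_anomaly = zd$r_jk, r_prm = zd$r_jh, diff = zd$diff,
                 ci_low = zd$ci_low, ci_high = zd$ci_high,
                 significant = zd$significant)
    }))
  }))

  # LMM layer (Table-4 style analog); the anomaly score enters standardized
  # so all fixed effects share comparable scales.
  subj$anomaly_z <- as.numeric(scale(subj$patient_score))
  base_terms <- c("age", "sex", "BMI", "factor(smoking_status)", "smoking_duration")
  lmm <- do.call(rbind, lapply(c("FEV1pp", "FEV1_FVC", "FRC", "FRC_TLC", "BODE"),
                               function(out) {
    do.call(rbind, lapply(c("pct_fsad", "pct_emph"), function(m) {
      f0 <- fit_lmm_and_lrt(subj, out, base_terms, c(base_terms, m))
      f1 <- fit_lmm_and_lrt(subj, out, c(base_terms, m),
                            c(base_terms, m, "anomaly_z"))
      data.frame(
        outcome = out, prm_term = m,
        r2_baseline = f0$baseline$r2[["adjusted_conditional_r2"]],
        r2_prm = f0$extended$r2[["adjusted_conditional_r2"]],
        r2_prm_anomaly = f1$extended$r2[["adjusted_conditional_r2"]],
        lrt_p_prm = f0$lrt_p, lrt_p_anomaly = f1$lrt_p
      )
    }))
  }))

  # Bland-Altman: PRM diseased volume vs each cluster volume (log scale)
  prm_disease <- subj$pct_emph + subj$pct_fsad
  ba <- do.call(rbind, lapply(cluster_cols, function(cl) {
    res <- tryCatch(
      bland_altman_regression_loa(prm_disease, 100 * subj[[cl]], scale = "log"),
      phenomap_validation_error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    data.frame(cluster = cl, intercept = res$bias_intercept,
               slope = res$bias_slope, loa_halfwidth = res$loa_halfwidth,
               n = res$n, n_excluded = res$n_excluded)
  }))

  out <- list(subject_table = subj, trend_tests = trend, correlations = cors,
              correlation_differences = zou, lmm_comparison = lmm)
  if (!is.null(ba)) out$bland_altman <- ba
  out
}

#' Generate a report from pipeline results
#'
#' Writes a Markdown report summarizing the stage outputs of a completed
#' [run_pipeline()] directory - per-stage distributions of PRM volumes,
#' anomaly scores and cluster volumes; the correlation table with bands
#' and Holm-adjusted p; the Zou correlation-difference table; the LMM
#' comparison table; and Bland-Altman parameters - plus PNG figures when
#' a graphics device is available.
#'
#' @param results_dir A [run_pipeline()] output directory.
#' @return Invisibly, the report path.
#' @export
make_report <- function(results_dir) {
  need <- c("stats/trend_tests.csv", "stats/correlations.csv",
            "stats/lmm_comparison.csv", "stats/subject_table.csv")
  missing <- need[!file.exists(file.path(results_dir, need))]
  if (length(missing)) {
    stop_validation(sprintf("stats outputs missing: %s",
                            paste(missing, collapse = ", ")))
  }
  trend <- utils::read.csv(file.path(results_dir, "stats/trend_tests.csv"))
  cors <- utils::read.csv(file.path(results_dir, "stats/correlations.csv"))
  lmm <- utils::read.csv(file.path(results_dir, "stats/lmm_comparison.csv"))
  subj <- utils::read.csv(file.path(results_dir, "stats/subject_table.csv"))
  ba_path <- file.path(results_dir, "stats/bland_altman.csv")
  zou_path <- file.path(results_dir, "stats/correlation_differences.csv")

  fig_dir <- file.path(results_dir, "report_figures")
  dir.create(fig_dir, showWarnings = FALSE)
  figs <- character(0)
  if (capabilities("png") || capabilities("cairo")) {
    figs <- c(figs, report_figures(subj, fig_dir))
  }

  md <- c(
    "# Cohort phenotyping report", "",
    sprintf("Results directory: `%s`", results_dir), "",
    "## Severity-stage trends", "",
    df_to_md(trend[, c("measure", "jt_statistic", "jt_z", "jt_p")]), "",
    "## Correlations with clinical data", "",
    df_to_md(cors), "",
    "## Linear mixed-model comparison", "",
    df_to_md(lmm), ""
  )
  if (file.exists(zou_path)) {
    md <- c(md, "## Correlation differences (Zou)", "",
            df_to_md(utils::read.csv(zou_path)), "")
  }
  if (file.exists(ba_path)) {
    md <- c(md, "## Bland-Altman agreement (log scale)", "",
            df_to_md(utils::read.csv(ba_path)), "")
  }
  if (length(figs)) {
    md <- c(md, "## Figures", "",
            sprintf("![](%s)", file.path("report_figures", basename(figs))), "")
  }
  path <- file.path(results_dir, "report.md")
  writeLines(md, path)
  invisible(path)
}

report_figures <- function(subj, fig_dir) {
  subj$stage <- factor(subj$stage, levels = stage_levels())
  figs <- character(0)
  plots <- list(
    stage_pct_emph = ggplot2::ggplot(subj, ggplot2::aes(stage, pct_emph)) +
      ggplot2::geom_boxplot() + ggplot2::labs(y = "PRM Emph (%)"),
    stage_pct_fsad = ggplot2::ggplot(subj, ggplot2::aes(stage, pct_fsad)) +
      ggplot2::geom_boxplot() + ggplot2::labs(y = "PRM fSAD (%)"),
    stage_anomaly = ggplot2::ggplot(subj, ggplot2::aes(stage, patient_score)) +
      ggplot2::geom_boxplot() + ggplot2::labs(y = "patient anomaly score (NLL)"),
    anomaly_vs_emph = ggplot2::ggplot(subj, ggplot2::aes(pct_emph, patient_score)) +
      ggplot2::geom_point() + ggplot2::geom_smooth(method = "lm", formula = y ~ x)
  )
  for (nm in names(plots)) {
    f <- file.path(fig_dir, paste0(nm, ".png"))
    ok <- tryCatch({
      ggplot2::ggsave(f, plots[[nm]], width = 5, height = 4, dpi = 100)
      TRUE
    }, error = function(e) FALSE)
    if (ok) figs <- c(figs, f)
  }
  figs
}

df_to_md <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, rows)
}
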