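#' Configuration for the synthetic paired-CT cohort generator
#'
#' Builds the full parameter set that [generate_cohort()] consumes. The
#' defaults describe a cohort of never-smoker controls and GOLD 0-4
#' subjects whose per-stage mean emphysema and functional small-airway
#' disease (fSAD) lesion burdens follow the class means reported for large
#' inspiratory/expiratory CT cohorts, and whose Hounsfield-unit (HU)
#' distributions are truncated normals placed so that each ground-truth
#' tissue class falls deterministically inside its parametric response
#' mapping (PRM) box. Clinical covariates are linear functions of the two
#' lesion burdens plus a per-site random intercept and Gaussian noise.
#'
#' @param n_per_stage Integer, subjects generated per severity stage
#'   (stages are `control`, `GOLD0` ... `GOLD4`).
#' @param grid_shape Integer vector of length 3, voxel grid dimensions.
#' @param voxel_spacing_mm Positive numeric vector of length 3, voxel
#'   spacing in millimetres (stored in the NIfTI header on export).
#' @param stage_burden_means Named list with numeric vectors `emph` and
#'   `fsad`, each of length 6 and monotone nondecreasing over stages:
#'   per-stage mean lesion fractions (unitless, in `[0, 1]`).
#' @param burden_concentration Concentration of the Beta distribution used
#'   to draw per-subject lesion fractions around the stage mean.
#' @param hu_models Per-tissue-class truncated-normal HU parameters for the
#'   inspiratory and expiratory volume; see Details.
#' @param clinical_coeffs Data frame describing the linear clinical model;
#'   one row per variable with columns `intercept`, `b_emph`, `b_fsad`,
#'   `b_site`, `noise_sd`, `min`, `max`.
#' @param n_sites Number of study sites; subjects are assigned round-robin.
#' @param site_sd Standard deviation of the latent per-site effect. Each
#'   site draws one standard-normal latent; a variable with site
#'   coefficient `b_site` receives `b_site * site_sd * z_site`.
#' @param seed Master seed; every subject derives an independent substream.
#'
#' @details The HU model must keep each tissue class inside the PRM
#' interval it is meant to occupy: emphysema voxels below -950 HU on
#' inspiration and below -856 HU on expiration, fSAD voxels in the normal
#' inspiratory band but below -856 HU on expiration, and normal voxels in
#' the normal band on both. The defaults satisfy this by construction, and
#' [cohort_config()] validates any replacement.
#'
#' @return An object of class `phenomap_cohort_config`.
#' @seealso [generate_cohort()], [generate_subject()], [write_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_per_stage = 2, seed = 1)
#' cfg$stage_burden_means$emph
cohort_config <- function(n_per_stage = 10,
                          grid_shape = c(64L, 64L, 48L),
                          voxel_spacing_mm = c(2.5, 2.5, 2.5),
                          stage_burden_means = default_stage_burden_means(),
                          burden_concentration = 30,
                          hu_models = default_hu_models(),
                          clinical_coeffs = default_clinical_coeffs(),
                          n_sites = 4,
                          site_sd = 1,
                          seed = 42L) {
  cfg <- structure(
    list(
      n_per_stage = as.integer(n_per_stage),
      grid_shape = as.integer(grid_shape),
      voxel_spacing_mm = as.numeric(voxel_spacing_mm),
      stage_burden_means = stage_burden_means,
      burden_concentration = burden_concentration,
      hu_models = hu_models,
      clinical_coeffs = clinical_coeffs,
      n_sites = as.integer(n_sites),
      site_sd = site_sd,
      seed = as.integer(seed)
    ),
    class = "phenomap_cohort_config"
  )
  validate_cohort_config(cfg)
}

#' Default per-stage mean lesion fractions
#'
#' Emphysema and fSAD burden means per stage (fractions, not percent),
#' calibrated to published per-GOLD-class PRM volume means.
#' @return Named list with `emph` and `fsad` length-6 numeric vectors.
#' @export
default_stage_burden_means <- function() {
  list(
    emph = c(control = 0.003, GOLD0 = 0.009, GOLD1 = 0.026,
             GOLD2 = 0.068, GOLD3 = 0.133, GOLD4 = 0.295),
    fsad = c(control = 0.071, GOLD0 = 0.147, GOLD1 = 0.220,
             GOLD2 = 0.289, GOLD3 = 0.394, GOLD4 = 0.451)
  )
}

#' Default truncated-normal HU models per tissue class
#'
#' Each entry gives `mean`, `sd`, `lower`, `upper` for the inspiratory and
#' expiratory HU draw of one ground-truth tissue class. Truncation bounds
#' are chosen so every class lands inside its intended PRM box.
#' @return Nested list `hu_models[[class]][[phase]]`.
#' @export
default_hu_models <- function() {
  tn <- function(mean, sd, lower, upper) {
    list(mean = mean, sd = sd, lower = lower, upper = upper)
  }
  list(
    normal = list(insp = tn(-870, 25, -950, -810), exp = tn(-740, 35, -856, -500)),
    emph   = list(insp = tn(-975, 12, -1000, -950), exp = tn(-945, 20, -1000, -856)),
    fsad   = list(insp = tn(-890, 25, -950, -810), exp = tn(-915, 20, -1000, -856)),
    body   = list(insp = tn(30, 20, -200, 100), exp = tn(30, 20, -200, 100))
  )
}

#' Default linear clinical model coefficients
#'
#' One row per clinical variable: `value = intercept + b_emph * emph +
#' b_fsad * fsad + b_site * site_sd * z_site + N(0, noise_sd)`, clipped to
#' `[min, max]`. Signs follow the known clinical correlates of emphysema
#' and air trapping (spirometry and walking distance decline with burden;
#' gas volumes, BODE and SGRQ increase).
#' @return A data frame with row names naming the variables.
#' @export
default_clinical_coeffs <- function() {
  df <- data.frame(
    intercept = c(98,    0.78,  2.8,  5.5,  0,    5,   520, 28,   58,   28),
    b_emph    = c(-160, -0.9,   3.5,  2.0,  8,    80, -420, 20,   10,   -6),
    b_fsad    = c(-70,  -0.5,   4.0,  1.6,  9,    90, -380, 18,   8,    0),
    b_site    = c(4,     0.02,  0.15, 0.2,  0.3,  3,  -15,  1.5,  0,    0),
    noise_sd  = c(8,     0.04,  0.45, 0.9,  0.8,  8,   60,  8,    7,    4.5),
    min       = c(10,    0.15,  1.0,  3.0,  0,    0,   50,  5,    45,   15),
    max       = c(150,   0.95,  9.0,  10.0, 10,   100, 800, 60,   80,   45)
  )
  rownames(df) <- c("FEV1pp", "FEV1_FVC", "FRC", "TLC", "BODE", "SGRQ",
                    "sixMWT", "smoking_duration", "age", "BMI")
  df
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_per_stage < 1L) stop_config("n_per_stage must be >= 1")
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8L)) {
    stop_config("grid_shape must be 3 integers, each >= 8")
  }
  if (length(cfg$voxel_spacing_mm) != 3L || any(cfg$voxel_spacing_mm <= 0)) {
    stop_config("voxel_spacing_mm must be 3 positive reals")
  }
  sbm <- cfg$stage_burden_means
  for (lesion in c("emph", "fsad")) {
    m <- sbm[[lesion]]
    if (length(m) != 6L || any(m < 0) || any(m > 1)) {
      stop_config(sprintf("stage_burden_means$%s must be 6 fractions in [0, 1]", lesion))
    }
    if (is.null(names(m))) {
      names(m) <- stage_levels()
      cfg$stage_burden_means[[lesion]] <- m
      sbm[[lesion]] <- m
    } else if (!identical(names(m), stage_levels())) {
      stop_config(sprintf("stage_burden_means$%s names must be %s",
                          lesion, paste(stage_levels(), collapse = ", ")))
    }
    if (any(diff(m) < 0)) {
      stop_config(sprintf("stage_burden_means$%s must be monotone nondecreasing", lesion))
    }
  }
  if (any(sbm$emph + sbm$fsad > 0.95)) {
    stop_config("combined stage burden means exceed 0.95: impossible lesion target")
  }
  if (cfg$burden_concentration <= 0) stop_config("burden_concentration must be positive")
  for (cls in c("normal", "emph", "fsad")) {
    for (phase in c("insp", "exp")) {
      p <- cfg$hu_models[[cls]][[phase]]
      if (is.null(p)) stop_config(sprintf("hu_models missing %s/%s", cls, phase))
      if (p$lower >= p$upper) stop_config("hu_models truncation bounds must satisfy lower < upper")
      if (p$lower < -1024 || p$upper > 100) {
        stop_config("hu_models bounds must lie in [-1024, 100]")
      }
    }
  }
  # Each lung tissue class must land inside the PRM box it is designed for.
  check_box <- function(cls, insp_lo, insp_hi, exp_lo, exp_hi) {
    p <- cfg$hu_models[[cls]]
    ok <- p$insp$lower >= insp_lo && p$insp$upper <= insp_hi &&
      p$exp$lower >= exp_lo && p$exp$upper <= exp_hi
    if (!ok) {
      stop_config(sprintf("hu_models$%s truncation bounds leave its PRM interval", cls))
    }
  }
  check_box("emph", -1000, -950, -1000, -856)
  check_box("fsad", -950, -810, -1000, -856)
  check_box("normal", -950, -810, -856, -500)
  cc <- cfg$clinical_coeffs
  needed <- c("intercept", "b_emph", "b_fsad", "b_site", "noise_sd", "min", "max")
  if (!is.data.frame(cc) || !all(needed %in% names(cc))) {
    stop_config(sprintf("clinical_coeffs must have columns: %s", paste(needed, collapse = ", ")))
  }
  if (cfg$n_sites < 1L) stop_config("n_sites must be >= 1")
  if (cfg$site_sd < 0) stop_config("site_sd must be >= 0")
  cfg
}

#' @export
print.phenomap_cohort_config <- function(x, ...) {
  cat("<phenomap cohort config>\n")
  cat(sprintf("  %d subjects per stage, %d sites, grid %s, seed %d\n",
              x$n_per_stage, x$n_sites, paste(x$grid_shape, collapse = "x"), x$seed))
  cat("  stage burden means (emph): ",
      paste(sprintf("%.3f", x$stage_burden_means$emph), collapse = " "), "\n")
  cat("  stage burden means (fsad): ",
      paste(sprintf("%.3f", x$stage_burden_means$fsad), collapse = " "), "\n")
  invisible(x)
}
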