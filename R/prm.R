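# Parametric response mapping (PRM) of paired insp/exp HU grids.
#
# HU boxes (joint inspiratory x expiratory intervals):
#   Emph:   insp in [-1000, -950],  exp in [-1000, -856)
#   fSAD:   insp in (-950,  -810],  exp in [-1000, -856)
#   Normal: insp in (-950,  -810],  exp in [-856,  -500]
# Anything else (airways, vessels, out-of-range attenuation) is Excluded.
# Boundary convention: -950 HU on inspiration belongs to Emph, -856 HU on
# expiration belongs to Normal; this makes the three boxes pairwise
# disjoint so every voxel receives exactly one label.

PRM_CODES <- c(background = 0L, Normal = 1L, fSAD = 2L, Emph = 3L, Excluded = 4L)

#' Classify paired HU values into PRM classes
#'
#' Vectorized voxel-wise PRM classification. Class labels are returned as
#' integer codes: 1 = Normal, 2 = fSAD, 3 = Emph, 4 = Excluded (use
#' [prm_class_names()] to decode).
#'
#' @param insp_hu,exp_hu Numeric vectors of equal length: inspiratory and
#'   registered expiratory HU at the same voxels.
#' @return Integer vector of PRM codes, same length as the inputs.
#' @export
#' @examples
#' classify_voxels(c(-960, -900, -900, -300), c(-900, -950, -700, -200))
classify_voxels <- function(insp_hu, exp_hu) {
  if (length(insp_hu) != length(exp_hu)) {
    stop_validation("insp_hu and exp_hu must have equal length")
  }
  assert_finite(insp_hu, "inspiratory HU")
  assert_finite(exp_hu, "expiratory HU")
  emph_insp <- insp_hu >= -1000 & insp_hu <= -950
  norm_insp <- insp_hu > -950 & insp_hu <= -810
  low_exp <- exp_hu >= -1000 & exp_hu < -856
  norm_exp <- exp_hu >= -856 & exp_hu <= -500
  out <- rep.int(PRM_CODES[["Excluded"]], length(insp_hu))
  out[emph_insp & low_exp] <- PRM_CODES[["Emph"]]
  out[norm_insp & low_exp] <- PRM_CODES[["fSAD"]]
  out[norm_insp & norm_exp] <- PRM_CODES[["Normal"]]
  out
}

#' Decode PRM integer codes
#' @param codes Integer vector of PRM codes (0-4).
#' @return Character vector of class names.
#' @export
prm_class_names <- function(codes) {
  names(PRM_CODES)[match(codes, PRM_CODES)]
}

#' Compute a subject's parametric response map
#'
#' Applies [classify_voxels()] over the lung mask and summarizes relative
#' class volumes. Percentages for Normal/fSAD/Emph are relative to the
#' PRM-classified lung voxels (so the three sum to 100); the Excluded
#' share is reported separately relative to all lung voxels. Low
#' attenuation areas LAA-950 (inspiration) and LAA-856 (expiration) are
#' included for reference.
#'
#' @param study A `phenomap_study` (see [generate_subject()]), or any list
#'   with `insp`, `exp_registered` and logical `lung_mask` arrays of equal
#'   shape.
#' @return An object of class `phenomap_prm`: the integer labelmap
#'   (0 background outside the lung) plus the summary percentages.
#' @export
compute_prm <- function(study) {
  insp <- study$insp
  expv <- study$exp_registered
  mask <- study$lung_mask
  if (is.null(insp) || is.null(expv) || is.null(mask)) {
    stop_validation("study must carry insp, exp_registered and lung_mask")
  }
  if (!identical(dim(insp), dim(expv)) || !identical(dim(insp), dim(mask))) {
    stop_dimension("insp, exp_registered and lung_mask must share shape")
  }
  lung <- which(mask)
  if (length(lung) == 0L) stop_validation("empty lung mask")
  labels <- classify_voxels(insp[lung], expv[lung])
  labelmap <- array(PRM_CODES[["background"]], dim = dim(insp))
  labelmap[lung] <- labels
  n_lung <- length(lung)
  n_classified <- sum(labels != PRM_CODES[["Excluded"]])
  pct_of_classified <- function(code) {
    if (n_classified == 0L) return(NA_real_)
    100 * sum(labels == code) / n_classified
  }
  structure(
    list(
      labelmap = labelmap,
      pct_normal = pct_of_classified(PRM_CODES[["Normal"]]),
      pct_fsad = pct_of_classified(PRM_CODES[["fSAD"]]),
      pct_emph = pct_of_classified(PRM_CODES[["Emph"]]),
      pct_excluded = 100 * sum(labels == PRM_CODES[["Excluded"]]) / n_lung,
      laa950_pct = laa_percent(insp, mask, -950),
      laa856_pct = laa_percent(expv, mask, -856),
      n_lung_voxels = n_lung,
      subject_id = study$subject_id %||% NA_character_
    ),
    class = "phenomap_prm"
  )
}

#' @export
print.phenomap_prm <- function(x, ...) {
  cat(sprintf("<PRM> Normal %.1f%% | fSAD %.1f%% | Emph %.1f%% (excluded %.2f%% of lung)\n",
              x$pct_normal, x$pct_fsad, x$pct_emph, x$pct_excluded))
  invisible(x)
}

#' Low attenuation area percentage
#'
#' Percentage of masked voxels with HU strictly below a threshold; with
#' `threshold_hu = -950` on an inspiratory grid this is LAA-950, with
#' `-856` on an expiratory grid LAA-856.
#'
#' @param hu Numeric array of HU values.
#' @param mask Logical array of the same shape.
#' @param threshold_hu Threshold in HU.
#' @return Percentage in `[0, 100]`.
#' @export
laa_percent <- function(hu, mask, threshold_hu) {
  if (!identical(dim(hu), dim(mask))) stop_dimension("hu and mask must share shape")
  n <- sum(mask)
  if (n == 0L) stop_validation("empty mask")
  100 * sum(hu[mask] < threshold_hu) / n
}

#' Tabulate PRM summaries over a cohort
#'
#' @param cohort A `phenomap_cohort`.
#' @return Data frame with one row per subject: percentages and LAA metrics.
#' @export
prm_cohort_table <- function(cohort) {
  rows <- lapply(cohort$subjects, function(s) {
    p <- compute_prm(s$study)
    data.frame(subject_id = s$study$subject_id,
               stage = as.character(s$study$stage),
               site_id = s$study$site_id,
               pct_normal = p$pct_normal, pct_fsad = p$pct_fsad,
               pct_emph = p$pct_emph, pct_excluded = p$pct_excluded,
               laa950_pct = p$laa950_pct, laa856_pct = p$laa856_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
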