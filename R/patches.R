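# Overlapping 3D patch extraction and fixed-length patch featurization.

#' Plan an overlapping patch grid over a lung mask
#'
#' Tiles the volume with cubic patches of side `patch_size` and stride
#' `round(patch_size * (1 - overlap_fraction))` per axis, starting at the
#' origin, with the final tile clamped so it ends at the volume edge.
#' Patches whose lung content falls below `min_lung_fraction` are dropped.
#' When an axis is shorter than `patch_size`, clamping (if enabled)
#' shrinks the patch extent to the axis length.
#'
#' @param mask Logical 3D array (lung mask).
#' @param patch_size Cube side in voxels (default 50).
#' @param overlap_fraction Fractional overlap between neighbouring patches
#'   (default 0.2, i.e. stride 40 for size-50 patches).
#' @param min_lung_fraction Minimum fraction of lung voxels a patch must
#'   contain to be kept (default 0.2).
#' @param clamp Allow per-axis shrinking when a dimension is shorter than
#'   `patch_size` (default TRUE).
#' @return An object of class `phenomap_patch_grid`: integer matrix
#'   `origins` (0-based corners, one row per kept patch), the per-axis
#'   effective `extent`, per-patch `lung_fraction`, and `coverage`, the
#'   fraction of lung voxels under the union of kept patches.
#' @export
#' @examples
#' m <- array(TRUE, c(60, 60, 60))
#' g <- plan_patches(m, patch_size = 50)
#' nrow(g$origins)
plan_patches <- function(mask, patch_size = 50L, overlap_fraction = 0.2,
                         min_lung_fraction = 0.2, clamp = TRUE) {
  d <- dim(mask)
  if (length(d) != 3L) stop_dimension("mask must be a 3D array")
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L) stop_validation("patch_size must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_validation("overlap_fraction must be in [0, 1)")
  }
  if (any(d < patch_size) && !clamp) {
    stop_dimension(sprintf(
      "mask dimensions (%s) smaller than patch_size %d and clamping disabled",
      paste(d, collapse = "x"), patch_size
    ))
  }
  extent <- pmin(patch_size, d)
  stride <- max(1L, as.integer(round(patch_size * (1 - overlap_fraction))))
  axis_origins <- function(dim_len, ext) {
    if (dim_len <= ext) return(0L)
    o <- seq.int(0L, dim_len - ext, by = stride)
    last <- dim_len - ext
    if (o[length(o)] != last) o <- c(o, last)
    as.integer(o)
  }
  ox <- axis_origins(d[1], extent[1])
  oy <- axis_origins(d[2], extent[2])
  oz <- axis_origins(d[3], extent[3])
  origins <- as.matrix(expand.grid(x = ox, y = oy, z = oz, KEEP.OUT.ATTRS = FALSE))
  storage.mode(origins) <- "integer"

  patch_vox <- prod(extent)
  lung_fraction <- vapply(seq_len(nrow(origins)), function(i) {
    o <- origins[i, ]
    sum(mask[(o[1] + 1L):(o[1] + extent[1]),
             (o[2] + 1L):(o[2] + extent[2]),
             (o[3] + 1L):(o[3] + extent[3])]) / patch_vox
  }, numeric(1))
  keep <- lung_fraction >= min_lung_fraction
  origins <- origins[keep, , drop = FALSE]
  lung_fraction <- lung_fraction[keep]

  covered <- array(FALSE, dim = d)
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, ]
    covered[(o[1] + 1L):(o[1] + extent[1]),
            (o[2] + 1L):(o[2] + extent[2]),
            (o[3] + 1L):(o[3] + extent[3])] <- TRUE
  }
  n_lung <- sum(mask)
  coverage <- if (n_lung > 0L) sum(mask & covered) / n_lung else 0

  structure(
    list(patch_size = patch_size, overlap_fraction = overlap_fraction,
         stride = stride, extent = as.integer(extent), origins = origins,
         lung_fraction = lung_fraction, coverage = coverage,
         min_lung_fraction = min_lung_fraction, grid_shape = d),
    class = "phenomap_patch_grid"
  )
}

#' @export
print.phenomap_patch_grid <- function(x, ...) {
  cat(sprintf("<patch grid> %d patches of %s (stride %d), lung coverage %.1f%%\n",
              nrow(x$origins), paste(x$extent, collapse = "x"), x$stride,
              100 * x$coverage))
  invisible(x)
}

#' Extract paired insp/exp patches for a planned grid
#'
#' @param study A `phenomap_study`.
#' @param grid A [plan_patches()] result planned on this study's mask.
#' @return List of patch records in `grid$origins` order, each with
#'   `insp`, `exp`, `mask` sub-arrays and the `origin`.
#' @export
extract_patch_pairs <- function(study, grid) {
  if (!identical(dim(study$lung_mask), grid$grid_shape)) {
    stop_dimension("grid was not planned on this study's mask shape")
  }
  ext <- grid$extent
  lapply(seq_len(nrow(grid$origins)), function(i) {
    o <- grid$origins[i, ]
    if (any(o < 0L) || any(o + ext > grid$grid_shape)) {
      abort_phenomap("patch origin out of bounds", "phenomap_internal_error")
    }
    ix <- (o[1] + 1L):(o[1] + ext[1])
    iy <- (o[2] + 1L):(o[2] + ext[2])
    iz <- (o[3] + 1L):(o[3] + ext[3])
    list(origin = o,
         insp = study$insp[ix, iy, iz],
         exp = study$exp_registered[ix, iy, iz],
         mask = study$lung_mask[ix, iy, iz])
  })
}

#' Deterministic histogram featurizer for a patch pair
#'
#' Fixed-length stand-in for learned patch representations: concatenates
#' lung-voxel HU histogram densities of the inspiratory and expiratory
#' patch, their means and standard deviations, and the patch-level
#' LAA-950 (inspiratory) and LAA-856 (expiratory) fractions, zero-padded
#' (or truncated) to dimension `d`.
#'
#' @param patch A patch record from [extract_patch_pairs()].
#' @param n_bins Histogram bins per phase (default 32).
#' @param hu_range HU range spanned by the bins (default `c(-1024, 0)`);
#'   values outside are clamped into the edge bins.
#' @param d Output dimension (default 512, zero-padded).
#' @return Numeric feature vector of length `d`.
#' @export
featurize_histogram <- function(patch, n_bins = 32L, hu_range = c(-1024, 0),
                                d = 512L) {
  lung <- patch$mask
  if (!any(lung)) stop_validation("patch contains no lung voxels")
  insp <- patch$insp[lung]
  expv <- patch$exp[lung]
  hist_density <- function(x) {
    x <- clip(x, hu_range[1], hu_range[2] - 1e-9)
    breaks <- seq(hu_range[1], hu_range[2], length.out = n_bins + 1L)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
    counts / length(x)
  }
  feats <- c(
    hist_density(insp), hist_density(expv),
    mean(insp) / 1000, stats::sd(insp) / 100,
    mean(expv) / 1000, stats::sd(expv) / 100,
    mean(insp < -950), mean(expv < -856)
  )
  feats[!is.finite(feats)] <- 0  # sd undefined for single-voxel patches
  if (length(feats) >= d) feats[seq_len(d)] else c(feats, numeric(d - length(feats)))
}

#' Embed a cohort into per-patch latent features
#'
#' Plans a patch grid per subject, extracts paired patches and applies the
#' chosen featurizer, returning one stacked feature matrix with patch
#' metadata (including per-patch emphysema and air-trapping fractions
#' used downstream for reference-patch selection).
#'
#' @param cohort A `phenomap_cohort`.
#' @param featurizer `"histogram"` (default, deterministic) or a
#'   `phenomap_encoder` from [train_contrastive_encoder()].
#' @param patch_size,overlap_fraction,min_lung_fraction Patch grid
#'   parameters, see [plan_patches()].
#' @param d Feature dimension for the histogram featurizer.
#' @return An object of class `phenomap_features`: `matrix`
#'   (`n_patches x d`), `meta` data frame (subject_id, stage, site_id,
#'   origin, lung_fraction, emph_pct, airtrap_pct), `featurizer_id`, and
#'   the per-subject `grids`.
#' @export
embed_cohort <- function(cohort, featurizer = "histogram",
                         patch_size = 50L, overlap_fraction = 0.2,
                         min_lung_fraction = 0.2, d = 512L) {
  is_encoder <- inherits(featurizer, "phenomap_encoder")
  if (!is_encoder && !identical(featurizer, "histogram")) {
    stop_config("featurizer must be \"histogram\" or a phenomap_encoder")
  }
  rows <- list()
  mats <- list()
  grids <- list()
  for (s in cohort$subjects) {
    grid <- plan_patches(s$study$lung_mask, patch_size, overlap_fraction,
                         min_lung_fraction)
    patches <- extract_patch_pairs(s$study, grid)
    if (length(patches) == 0L) next
    feats <- t(vapply(patches, function(p) {
      if (is_encoder) encode_patch(featurizer, p) else {
        featurize_histogram(p, d = d)
      }
    }, numeric(if (is_encoder) featurizer$d_out else d)))
    meta <- data.frame(
      subject_id = s$study$subject_id,
      stage = as.character(s$study$stage),
      site_id = s$study$site_id,
      origin_x = grid$origins[, 1], origin_y = grid$origins[, 2],
      origin_z = grid$origins[, 3],
      lung_fraction = grid$lung_fraction,
      emph_pct = vapply(patches, function(p) 100 * mean(p$insp[p$mask] < -950), numeric(1)),
      airtrap_pct = vapply(patches, function(p) 100 * mean(p$exp[p$mask] < -856), numeric(1)),
      stringsAsFactors = FALSE
    )
    mats[[length(mats) + 1L]] <- feats
    rows[[length(rows) + 1L]] <- meta
    grids[[s$study$subject_id]] <- grid
  }
  if (length(mats) == 0L) stop_validation("no patches extracted from cohort")
  mat <- do.call(rbind, mats)
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  if (!all(is.finite(mat))) stop_validation("non-finite feature values")
  structure(
    list(matrix = mat, meta = meta,
         featurizer_id = if (is_encoder) featurizer$id else "histogram",
         grids = grids),
    class = "phenomap_features"
  )
}

#' @export
print.phenomap_features <- function(x, ...) {
  cat(sprintf("<latent features> %d patches x %d dims (%s) from %d subjects\n",
              nrow(x$matrix), ncol(x$matrix), x$featurizer_id,
              length(unique(x$meta$subject_id))))
  invisible(x)
}
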