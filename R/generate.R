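# Synthetic paired-CT subject and cohort generation.

# Two-ellipsoid lung mask (left/right lung) inside the voxel grid.
make_lung_mask <- function(grid_shape) {
  d <- grid_shape
  ax <- seq_len(d[1]) - 0.5
  ay <- seq_len(d[2]) - 0.5
  az <- seq_len(d[3]) - 0.5
  centers <- list(c(0.28, 0.5, 0.5) * d, c(0.72, 0.5, 0.5) * d)
  semi <- c(0.21, 0.45, 0.46) * d
  mask <- array(FALSE, dim = d)
  for (ctr in centers) {
    qx <- ((ax - ctr[1]) / semi[1])^2
    qy <- ((ay - ctr[2]) / semi[2])^2
    qz <- ((az - ctr[3]) / semi[3])^2
    q <- outer(outer(qx, qy, `+`), qz, `+`)
    mask <- mask | (q <= 1)
  }
  mask
}

# Grow spherical lesion blobs over currently-normal lung voxels until
# exactly `target_n` voxels are labelled; the last blob is trimmed at
# random so the drawn burden fraction is met to the voxel.
place_lesions <- function(lung_coords, available, target_n,
                          radius_range = c(2, 5)) {
  chosen <- integer(0)
  n_left <- target_n
  avail <- available
  while (n_left > 0L) {
    if (!any(avail)) break  # lung saturated; caller validates targets
    idx_avail <- which(avail)
    ctr_i <- idx_avail[sample.int(length(idx_avail), 1L)]
    ctr <- lung_coords[ctr_i, ]
    r <- stats::runif(1, radius_range[1], radius_range[2])
    d2 <- (lung_coords[, 1] - ctr[1])^2 +
      (lung_coords[, 2] - ctr[2])^2 +
      (lung_coords[, 3] - ctr[3])^2
    blob <- which(d2 <= r^2 & avail)
    if (length(blob) > n_left) {
      blob <- blob[sample.int(length(blob), n_left)]
    }
    chosen <- c(chosen, blob)
    avail[blob] <- FALSE
    n_left <- target_n - length(chosen)
  }
  chosen
}

#' Generate one synthetic subject with paired CT, ground truth, and clinicals
#'
#' Draws a paired inspiratory/expiratory HU volume with a two-ellipsoid
#' lung mask, a ground-truth tissue labelmap (normal / emphysema / fSAD)
#' built from spherical lesion blobs whose total burden is Beta-drawn
#' around the stage mean, and a clinical record linearly linked to the
#' lesion burdens. The expiratory volume is emitted on the same grid,
#' i.e. already voxelwise registered to inspiration.
#'
#' @param stage One of `"control"`, `"GOLD0"` ... `"GOLD4"` (or `0:4`).
#' @param config A [cohort_config()].
#' @param seed Integer substream seed; the same `(stage, config, seed)`
#'   always reproduces the identical subject.
#' @param subject_id Identifier string stored in all outputs.
#' @param site_id Integer site label in `1..n_sites`.
#' @param site_effect Latent standard-normal site draw (scaled internally
#'   by `site_sd` and each variable's site coefficient). Drawn from the
#'   subject stream when `NULL`.
#' @return A list with components `study` (class `phenomap_study`),
#'   `truth` (tissue labelmap and burden fractions), and `clinical`
#'   (one-row data frame).
#' @export
#' @examples
#' s <- generate_subject("GOLD2", cohort_config(seed = 1), seed = 7)
#' s$truth$emph_fraction
generate_subject <- function(stage, config, seed,
                             subject_id = NULL, site_id = 1L,
                             site_effect = NULL) {
  stage <- as_stage(stage)
  stage_chr <- as.character(stage)
  if (is.null(subject_id)) subject_id <- sprintf("%s_s%06d", stage_chr, seed %% 1000000L)
  d <- config$grid_shape
  with_seed(seed, {
    mask <- make_lung_mask(d)
    lung_idx <- which(mask)
    n_lung <- length(lung_idx)
    lung_coords <- which(mask, arr.ind = TRUE)

    mean_e <- config$stage_burden_means$emph[[stage_chr]]
    mean_f <- config$stage_burden_means$fsad[[stage_chr]]
    conc <- config$burden_concentration
    # Subject burden ~ Beta around the stage mean. For small means the
    # concentration is inflated so the first shape parameter never drops
    # below 1: a shape below 1 puts a spike at zero with a heavy upper
    # tail, producing rare "controls" carrying more lesion than a GOLD 2
    # class mean, which contradicts the narrow printed dispersion of the
    # healthy classes.
    draw_frac <- function(m) {
      if (m <= 0) return(0)
      if (m >= 1) return(1)
      c_eff <- max(conc, 1 / m)
      stats::rbeta(1, m * c_eff, (1 - m) * c_eff)
    }
    frac_e <- draw_frac(mean_e)
    frac_f <- draw_frac(mean_f)
    if (frac_e + frac_f > 0.95) frac_f <- max(0, 0.95 - frac_e)
    if (mean_e + mean_f > 0.95) {
      stop_config("impossible lesion burden: combined target fraction > 0.95")
    }

    # labels over lung voxels: 1 normal, 2 fsad, 3 emph (matches PRM codes)
    labels <- rep(1L, n_lung)
    n_e <- round(frac_e * n_lung)
    n_f <- round(frac_f * n_lung)
    avail <- rep(TRUE, n_lung)
    emph_vox <- place_lesions(lung_coords, avail, n_e)
    labels[emph_vox] <- 3L
    avail[emph_vox] <- FALSE
    fsad_vox <- place_lesions(lung_coords, avail, n_f)
    labels[fsad_vox] <- 2L

    hu <- config$hu_models
    draw_hu <- function(model, n) rnorm_trunc(n, model$mean, model$sd, model$lower, model$upper)
    insp <- array(0, dim = d)
    expv <- array(0, dim = d)
    body_idx <- which(!mask)
    insp[body_idx] <- draw_hu(hu$body$insp, length(body_idx))
    expv[body_idx] <- draw_hu(hu$body$exp, length(body_idx))
    class_codes <- c(normal = 1L, fsad = 2L, emph = 3L)
    for (nm in names(class_codes)) {
      vox <- lung_idx[labels == class_codes[[nm]]]
      insp[vox] <- draw_hu(hu[[nm]]$insp, length(vox))
      expv[vox] <- draw_hu(hu[[nm]]$exp, length(vox))
    }

    labelmap <- array(0L, dim = d)
    labelmap[lung_idx] <- labels
    emph_fraction <- sum(labels == 3L) / n_lung
    fsad_fraction <- sum(labels == 2L) / n_lung

    if (is.null(site_effect)) site_effect <- stats::rnorm(1)
    clinical <- draw_clinical(config, emph_fraction, fsad_fraction,
                              site_effect, stage_chr)
    clinical <- cbind(
      data.frame(subject_id = subject_id, stage = stage_chr,
                 site_id = as.integer(site_id), stringsAsFactors = FALSE),
      clinical
    )

    study <- structure(
      list(subject_id = subject_id, insp = insp, exp_registered = expv,
           lung_mask = mask, stage = stage, site_id = as.integer(site_id),
           voxel_spacing_mm = config$voxel_spacing_mm),
      class = "phenomap_study"
    )
    truth <- list(tissue_labelmap = labelmap,
                  emph_fraction = emph_fraction,
                  fsad_fraction = fsad_fraction)
    list(study = study, truth = truth, clinical = clinical)
  })
}

draw_clinical <- function(config, emph, fsad, site_effect, stage_chr) {
  cc <- config$clinical_coeffs
  vals <- cc$intercept + cc$b_emph * emph + cc$b_fsad * fsad +
    cc$b_site * config$site_sd * site_effect +
    stats::rnorm(nrow(cc), 0, cc$noise_sd)
  vals <- clip(vals, cc$min, cc$max)
  names(vals) <- rownames(cc)
  out <- as.data.frame(as.list(vals))
  # Controls are never-smokers: no smoking history by definition.
  if (stage_chr == "control") {
    out$smoking_duration <- 0
    smoking_status <- 0L
  } else {
    smoking_status <- sample(c(1L, 2L), 1L)
  }
  out$FRC <- pmin(out$FRC, out$TLC - 0.05)  # physical constraint TLC >= FRC
  out$FRC_TLC <- out$FRC / out$TLC
  out$smoking_status <- smoking_status
  out$sex <- sample(c("f", "m"), 1L)
  out
}

#' Generate a full synthetic cohort
#'
#' Produces `n_per_stage` subjects for each of the six severity stages,
#' with round-robin site assignment and per-subject independent RNG
#' substreams derived from the master seed, so the cohort is reproducible
#' as a whole and subject-by-subject.
#'
#' @param config A [cohort_config()].
#' @return An object of class `phenomap_cohort`: a list with `subjects`
#'   (list of [generate_subject()] triples), `clinical` (stacked data
#'   frame), `truth` (per-subject burden table) and `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_per_stage = 1, seed = 3))
#' nrow(coh$clinical)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  stages <- stage_levels()
  site_effects <- with_seed(derive_seed(config$seed, 0L),
                            stats::rnorm(config$n_sites))
  subjects <- list()
  k <- 0L
  for (si in seq_along(stages)) {
    for (i in seq_len(config$n_per_stage)) {
      k <- k + 1L
      site_id <- ((k - 1L) %% config$n_sites) + 1L
      sid <- sprintf("%s_%03d", stages[si], i)
      subjects[[k]] <- generate_subject(
        stages[si], config,
        seed = derive_seed(config$seed, k),
        subject_id = sid, site_id = site_id,
        site_effect = site_effects[site_id]
      )
    }
  }
  clinical <- do.call(rbind, lapply(subjects, `[[`, "clinical"))
  truth <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$clinical$subject_id, stage = s$clinical$stage,
               emph_fraction = s$truth$emph_fraction,
               fsad_fraction = s$truth$fsad_fraction,
               stringsAsFactors = FALSE)
  }))
  rownames(clinical) <- rownames(truth) <- NULL
  structure(list(subjects = subjects, clinical = clinical, truth = truth,
                 config = config),
            class = "phenomap_cohort")
}

#' @export
print.phenomap_cohort <- function(x, ...) {
  cat(sprintf("<phenomap cohort> %d subjects (%d per stage), grid %s\n",
              length(x$subjects), x$config$n_per_stage,
              paste(x$config$grid_shape, collapse = "x")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits, per subject, the inspiratory, registered expiratory, lung-mask
#' and ground-truth labelmap volumes as NIfTI (`.nii.gz`, voxel spacing in
#' the header), plus one cohort-level clinical CSV, one ground-truth CSV,
#' and a JSON manifest recording all paths and the generating
#' configuration.
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!inherits(cohort, "phenomap_cohort")) stop_validation("expected a phenomap_cohort")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_validation(sprintf("cannot create directory: %s", out_dir))
  spacing <- cohort$config$voxel_spacing_mm
  write_vol <- function(arr, path) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
    path
  }
  vol_entries <- lapply(cohort$subjects, function(s) {
    sid <- s$study$subject_id
    base <- file.path(out_dir, sid)
    list(
      subject_id = sid,
      insp = write_vol(s$study$insp, paste0(base, "_insp.nii.gz")),
      exp_registered = write_vol(s$study$exp_registered, paste0(base, "_exp.nii.gz")),
      lung_mask = write_vol(s$study$lung_mask + 0L, paste0(base, "_mask.nii.gz")),
      truth_labelmap = write_vol(s$truth$tissue_labelmap, paste0(base, "_truth.nii.gz"))
    )
  })
  clinical_csv <- file.path(out_dir, "clinical.csv")
  truth_csv <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(cohort$clinical, clinical_csv, row.names = FALSE)
  utils::write.csv(cohort$truth, truth_csv, row.names = FALSE)
  manifest <- list(
    seed = cohort$config$seed,
    n_subjects = length(cohort$subjects),
    clinical_csv = clinical_csv,
    truth_csv = truth_csv,
    volumes = vol_entries,
    config = serialize_config(cohort$config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$clinical_coeffs <- cbind(variable = rownames(config$clinical_coeffs),
                               config$clinical_coeffs)
  out
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return A `phenomap_cohort`-like list with studies reloaded from NIfTI.
#' @export
read_cohort <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop_validation(sprintf("no manifest.json under %s", dir))
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  clinical <- utils::read.csv(mf$clinical_csv, stringsAsFactors = FALSE)
  truth <- utils::read.csv(mf$truth_csv, stringsAsFactors = FALSE)
  read_plain <- function(path, integer = FALSE) {
    img <- RNifti::readNifti(path)
    a <- array(if (integer) as.integer(img) else as.numeric(img), dim = dim(img))
    a
  }
  subjects <- lapply(seq_len(nrow(mf$volumes)), function(i) {
    row <- mf$volumes[i, ]
    cl <- clinical[clinical$subject_id == row$subject_id, , drop = FALSE]
    tr <- truth[truth$subject_id == row$subject_id, , drop = FALSE]
    mask <- read_plain(row$lung_mask, integer = TRUE) > 0
    labelmap <- read_plain(row$truth_labelmap, integer = TRUE)
    study <- structure(
      list(subject_id = row$subject_id,
           insp = read_plain(row$insp),
           exp_registered = read_plain(row$exp_registered),
           lung_mask = mask,
           stage = as_stage(cl$stage),
           site_id = cl$site_id,
           voxel_spacing_mm = as.numeric(mf$config$voxel_spacing_mm)),
      class = "phenomap_study"
    )
    list(study = study,
         truth = list(tissue_labelmap = labelmap,
                      emph_fraction = tr$emph_fraction,
                      fsad_fraction = tr$fsad_fraction),
         clinical = cl)
  })
  structure(list(subjects = subjects, clinical = clinical, truth = truth,
                 config = mf$config),
            class = "phenomap_cohort")
}
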