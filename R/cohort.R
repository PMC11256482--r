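#' Resample a volume through a displacement field (no degradation)
#'
#' Pull-back resampling: `out(x) = vol(x + u(x))`.
#'
#' @param vol a `morpho_volume`.
#' @param field a `morpho_field` on the same grid.
#' @param interpolation `"linear"` for intensities, `"nearest"` for labels.
#' @return resampled `morpho_volume`.
#' @export
warp_volume <- function(vol, field, interpolation = "linear") {
  stopifnot(is_volume(vol))
  d <- grid_dim(vol)
  if (!all(dim(field$data)[1:3] == d)) stop("field and volume geometry differ")
  xyz <- voxel_world_coords(vol)
  u <- cbind(as.vector(field$data[, , , 1]), as.vector(field$data[, , , 2]),
             as.vector(field$data[, , , 3]))
  vals <- sample_volume(vol, xyz + u, interpolation = interpolation)
  out <- volume(array(vals, d), spacing = vol$spacing, affine = vol$affine,
                units = vol$units)
  attr(out, "names_table") <- attr(vol, "names_table")
  out
}

#' Default irradiation effect specification
#'
#' The planted study effects: early white-matter contraction and restricted
#' diffusion (1 month), late cortical expansion and reduced blood volume
#' (6 months). Deformation magnitudes (centre Jacobian 0.8 in the corpus
#' callosum, reciprocal 1.25 in cortex, 1.6 mm Gaussian radius) are sized
#' so the recovered group contrast is about three times the between-subject
#' log-Jacobian standard deviation at the default cohort size -- an
#' adequately powered design, as a planned animal study would use. MD is
#' reduced to ~0.77 of control and CBV to ~0.74-0.75 of control, the
#' relative group differences typical of late radiation injury.
#'
#' @return nested list with `deformation`, `md`, `cbv` entries.
#' @export
default_effects <- function() {
  list(
    deformation = list(
      list(timepoint = "1M", structure = "corpus_callosum",
           volume_ratio = 0.78, sigma = 1.8),
      list(timepoint = "6M", structure = "cortex",
           volume_ratio = 1.5, sigma = 1.8)
    ),
    md = list(
      list(timepoint = "1M", structure = "corpus_callosum", factor = 0.77),
      list(timepoint = "1M", structure = "cortex", factor = 0.77)
    ),
    cbv = list(
      list(timepoint = "6M", structure = "corpus_callosum", factor = 0.74),
      list(timepoint = "6M", structure = "cortex", factor = 0.75)
    )
  )
}

# Physical centre of a focal blob planted in a named phantom structure.
effect_blob_center <- function(spec, structure) {
  centre <- spec$grid_shape * spec$spacing / 2
  ax <- spec$brain_axes
  switch(structure,
         corpus_callosum = centre + c(0, 0, 0.22 * ax[3]),
         cortex = centre + c(0.82 * ax[1], 0, 0),
         striatum = centre + c(-0.35 * ax[1], 0, -0.1 * ax[3]),
         stop("no blob anchor defined for structure: ", structure))
}

#' Generate a synthetic two-group longitudinal cohort on disk
#'
#' Writes, per subject and timepoint, a degraded T2w volume, a simulated
#' diffusion series with its b-table, a pre/post-contrast T2* pair, the
#' subject's ground-truth label map and ground-truth forward displacement
#' field (template -> subject), plus a `metadata.csv` tying them together.
#' Irradiated subjects at the affected timepoints receive the focal
#' deformations, MD decrements and CBV decrements in `effects`; both groups
#' receive subject-specific smooth anatomical jitter, bias fields and
#' Rician noise. Fully reproducible from `seed`.
#'
#' @param out_dir output directory (created).
#' @param n_per_cell subjects per group (>= 2).
#' @param timepoints character subset of `c("1M", "3M", "6M")`.
#' @param effects effect specification, see [default_effects()]; use
#'   `NULL` for a null cohort (groups exchangeable).
#' @param spec a [phantom_spec()].
#' @param seed master RNG seed.
#' @param jitter_mm peak amplitude of per-subject smooth anatomical jitter.
#' @param texture_amplitudes,texture_scales,texture_seed intra-tissue
#'   texture shared by the whole cohort (see [add_texture()]); zero
#'   amplitudes disable it. The texture is part of the anatomy definition
#'   (one fixed template anatomy, like a single inbred strain), so its seed
#'   is a separate constant rather than a function of the cohort seed.
#' @param dwi_snr,t2s_snr signal-to-noise (baseline signal / Rician sigma)
#'   of the simulated diffusion and T2* series.
#' @param protocol a [dwi_protocol()].
#' @param contrast a [contrast_protocol()].
#' @param compress write `.nii.gz` instead of `.nii`.
#' @return a `study_dataset`: `dir`, `metadata` (data.frame), generator
#'   parameters.
#' @export
make_cohort <- function(out_dir, n_per_cell = 6L,
                        timepoints = c("1M", "3M", "6M"),
                        effects = default_effects(),
                        spec = phantom_spec(), seed = 1L,
                        jitter_mm = 0.04,
                        texture_amplitudes = c(0.15, 0.15),
                        texture_scales = c(1.5, 4),
                        texture_seed = 7L,
                        dwi_snr = 40, t2s_snr = 80,
                        protocol = dwi_protocol(),
                        contrast = contrast_protocol(),
                        compress = FALSE) {
  if (n_per_cell < 2) stop("n_per_cell must be >= 2 (group statistics undefined)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  if (is.null(effects)) effects <- list(deformation = list(), md = list(), cbv = list())

  base <- make_phantom(spec)
  if (any(texture_amplitudes > 0))
    base$volume <- add_texture(base$volume, texture_amplitudes,
                               texture_scales, seed = texture_seed)
  groups <- c("control", "irradiated")
  subjects <- data.frame(
    subject_id = c(sprintf("C%02d", seq_len(n_per_cell)),
                   sprintf("IR%02d", seq_len(n_per_cell))),
    group = rep(groups, each = n_per_cell),
    stringsAsFactors = FALSE
  )
  rows <- merge(subjects, data.frame(timepoint = timepoints),
                by = NULL, sort = FALSE)
  rows <- rows[order(rows$timepoint, rows$group, rows$subject_id), ]
  seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 10L, nrow(rows)))

  pick <- function(lst, tp) Filter(function(e) e$timepoint == tp, lst)
  meta <- NULL
  for (r in seq_len(nrow(rows))) {
    sid <- rows$subject_id[r]; grp <- rows$group[r]; tp <- rows$timepoint[r]
    sseed <- seeds[r]

    # ground-truth forward field: planted effects (irradiated only) + jitter
    defs <- if (grp == "irradiated") {
      lapply(pick(effects$deformation, tp), function(e)
        focal_deformation(effect_blob_center(spec, e$structure),
                          sigma = e$sigma, volume_ratio = e$volume_ratio))
    } else list()
    eff <- make_deformation(defs, base$volume)
    u <- eff$field$data
    if (jitter_mm > 0) {
      jit <- withr_seed(sseed + 4L, {
        j <- array(stats::rnorm(prod(spec$grid_shape) * 3), c(spec$grid_shape, 3))
        for (c in 1:3) j[, , , c] <- gaussian_smooth3(j[, , , c], sigma = 4)
        j / max(abs(j)) * jitter_mm
      })
      u <- u + jit
    }
    fwd <- displacement_field(u, spacing = spec$spacing,
                              affine = base$volume$affine)
    inv <- invert_displacement(fwd)

    t2w <- warp_and_degrade(base$volume, inv, spec, seed = sseed)
    labs <- warp_volume(base$labels, inv, interpolation = "nearest")

    mdf <- if (grp == "irradiated") {
      e <- pick(effects$md, tp)
      stats::setNames(vapply(e, `[[`, 0, "factor"),
                      vapply(e, `[[`, "", "structure"))
    } else c()
    tens <- tensors_from_labels(labs, md_factors = mdf)
    dwi <- simulate_dwi(tens, protocol, noise_sigma = protocol$s0 / dwi_snr,
                        seed = sseed + 1L)

    cbvf <- if (grp == "irradiated") {
      e <- pick(effects$cbv, tp)
      stats::setNames(vapply(e, `[[`, 0, "factor"),
                      vapply(e, `[[`, "", "structure"))
    } else c()
    cbv <- cbv_from_labels(labs, cbv_factors = cbvf)
    pre <- volume(array(100 + 700 * (labs$data > 0), grid_dim(labs)),
                  spacing = labs$spacing, affine = labs$affine)
    t2s <- simulate_t2star(cbv, contrast, pre,
                           noise_sigma = 800 / t2s_snr, seed = sseed + 2L)

    stem <- paste0(sid, "_", tp)
    # metadata stores cohort-relative filenames so a cohort directory is
    # relocatable and byte-identical across output locations
    fnames <- list(
      t2w = paste0(stem, "_T2w", ext),
      dwi = paste0(stem, "_dwi", ext),
      t2s_pre = paste0(stem, "_t2s_pre", ext),
      t2s_post = paste0(stem, "_t2s_post", ext),
      labels = paste0(stem, "_labels", ext),
      truth_field = paste0(stem, "_truthfield", ext)
    )
    write_volume(t2w, file.path(out_dir, fnames$t2w))
    write_volume(dwi, file.path(out_dir, fnames$dwi))
    write_volume(t2s$pre, file.path(out_dir, fnames$t2s_pre))
    write_volume(t2s$post, file.path(out_dir, fnames$t2s_post))
    write_volume(labs, file.path(out_dir, fnames$labels))
    write_field(fwd, file.path(out_dir, fnames$truth_field))
    meta <- rbind(meta, data.frame(subject_id = sid, group = grp,
                                   timepoint = tp,
                                   as.data.frame(fnames,
                                                 stringsAsFactors = FALSE),
                                   stringsAsFactors = FALSE))
  }
  write_btable(protocol$bvals, protocol$bvecs,
               file.path(out_dir, "dwi.bval"), file.path(out_dir, "dwi.bvec"))
  utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(phantom_label_names(),
                   file.path(out_dir, "structure_names.csv"),
                   row.names = FALSE)
  jsonlite::write_json(effects, file.path(out_dir, "effects.json"),
                       auto_unbox = TRUE, digits = NA)
  path_cols <- c("t2w", "dwi", "t2s_pre", "t2s_post", "labels",
                 "truth_field")
  for (pc in path_cols) meta[[pc]] <- file.path(out_dir, meta[[pc]])
  structure(list(dir = out_dir, metadata = meta, spec = spec,
                 effects = effects, protocol = protocol,
                 contrast = contrast, seed = seed),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d scans (%d subjects x %d timepoints) in %s\n",
              nrow(x$metadata), length(unique(x$metadata$subject_id)),
              length(unique(x$metadata$timepoint)), x$dir))
  invisible(x)
}

#' Load a cohort previously written by [make_cohort()]
#' @param dir cohort directory containing `metadata.csv`.
#' @return a `study_dataset` (metadata and paths only).
#' @export
load_cohort <- function(dir) {
  mpath <- file.path(dir, "metadata.csv")
  if (!file.exists(mpath)) stop("no metadata.csv under ", dir)
  meta <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  for (pc in intersect(c("t2w", "dwi", "t2s_pre", "t2s_post", "labels",
                         "truth_field"), names(meta)))
    meta[[pc]] <- ifelse(file.exists(meta[[pc]]), meta[[pc]],
                         file.path(dir, meta[[pc]]))
  structure(list(dir = dir, metadata = meta), class = "study_dataset")
}
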