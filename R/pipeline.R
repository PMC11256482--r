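#' Configuration for an end-to-end DBM study
#'
#' Bundles every stage parameter and seed so a run is fully specified by
#' (cohort, config); the run manifest records all of it.
#'
#' @param alpha voxel-wise FWE level of the group comparison.
#' @param n_perm permutation budget of the maxT correction.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @param seed master seed (permutations).
#' @param affine_kind affine stage family (`"rigid"`, `"similarity"`,
#'   `"affine"`) or `"none"` to skip straight to the nonlinear stage.
#' @param affine_maxit per-level iteration caps of the affine stage.
#' @param template_align,template_iterations template construction options
#'   (see [build_template()]).
#' @param demons_levels,demons_iterations,sigma_update,sigma_total demons
#'   schedule and regularisation (see [register_nonlinear()]).
#' @param stat voxel statistic for [fwe_correct()] (`"pseudo-t"` or `"t"`).
#' @param logj_smooth Gaussian sigma in mm applied to log-Jacobian maps
#'   before voxel statistics (0 disables); converted to per-axis voxel
#'   sigmas so smoothing is isotropic in world space.
#' @param te echo time (s) of the T2* pair.
#' @param contrast a [contrast_protocol()].
#' @param min_cluster_voxels clusters smaller than this are dropped from
#'   the report (spurious single-voxel components).
#' @return a `dbm_config` list.
#' @export
dbm_config <- function(alpha = 0.01, n_perm = 1000L, connectivity = 26L,
                       seed = 1L, affine_kind = "rigid",
                       affine_maxit = c(120L, 60L, 20L),
                       template_align = "none", template_iterations = 1L,
                       demons_levels = c(4L, 2L, 1L),
                       demons_iterations = c(60L, 30L, 30L),
                       sigma_update = 1, sigma_total = 0.5,
                       stat = "pseudo-t",
                       logj_smooth = 0.6, te = 0.013,
                       contrast = contrast_protocol(te = te),
                       min_cluster_voxels = 5L) {
  structure(as.list(environment()), class = "dbm_config")
}

#' Run the full deformation-based morphometry study
#'
#' Orchestrates, per timepoint: brain masking and bias correction of every
#' T2w volume, mean-control template construction, affine + nonlinear
#' registration of every subject to the template, log-Jacobian maps,
#' voxel-wise permutation statistics with FWE control, signed cluster
#' extraction and atlas naming, quantitative CBV and diffusion maps warped
#' to template space, per-ROI study table, two-way ANOVA with LSD post-hoc
#' tests and Pearson correlation matrices (pooled and anchored). Writes CSV
#' outputs and a JSON run manifest; deterministic given (cohort, config).
#'
#' @param cohort a `study_dataset` (from [make_cohort()] or
#'   [load_cohort()]).
#' @param config a [dbm_config()].
#' @param out_dir output directory for CSVs and the manifest (`NULL` to
#'   skip writing).
#' @param atlas optional list with `labels`, `reference`, `naming`; default
#'   uses the clean phantom as its own atlas.
#' @param verbose print stage progress.
#' @return a `dbm_study` object; see Details.
#' @details The returned object holds per-timepoint `templates`, `masks`,
#'   `logj` map lists, `sigmask`s, `clusters`, `overlap` tables and
#'   `proportions`, plus the pooled `study_table`, `anova` results per
#'   parameter, `correlations` (pooled and anchored) and the `manifest`.
#' @export
run_dbm_study <- function(cohort, config = dbm_config(), out_dir = NULL,
                          atlas = NULL, verbose = FALSE) {
  stopifnot(inherits(cohort, "study_dataset"), inherits(config, "dbm_config"))
  meta <- cohort$metadata
  tps <- unique(meta$timepoint)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- new_manifest("dbm-study")
  manifest_add(manifest, "config", params = config[!vapply(config, is.object, TRUE)])

  if (is.null(atlas)) {
    spec <- if (!is.null(cohort$spec)) cohort$spec else phantom_spec()
    ph <- make_phantom(spec)
    atlas <- list(labels = ph$labels, reference = ph$volume,
                  naming = phantom_label_names())
  }

  btab_path <- file.path(cohort$dir, c("dwi.bval", "dwi.bvec"))
  btab <- read_btable(btab_path[1], btab_path[2])

  results <- list()
  study_rows <- NULL
  roi_masks <- list()   # template-space cluster ROIs, per timepoint

  for (tp in tps) {
    say("timepoint %s: preprocessing", tp)
    sel <- meta[meta$timepoint == tp, ]
    n_sub <- nrow(sel)
    t2w <- masks <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      v <- read_volume(file.path_abs(sel$t2w[i], cohort$dir))
      m <- brain_mask(v)
      t2w[[i]] <- bias_correct(v, m)
      masks[[i]] <- m
    }
    ctrl <- which(sel$group == "control")
    if (length(ctrl) == 0) stop("no control subjects at timepoint ", tp)
    say("timepoint %s: template from %d controls", tp, length(ctrl))
    template <- build_template(t2w[ctrl], align = config$template_align,
                               iterations = config$template_iterations,
                               maxit = config$affine_maxit)
    tmask <- brain_mask(template)

    say("timepoint %s: registration of %d subjects", tp, n_sub)
    logj <- vector("list", n_sub)
    regs <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      init <- if (config$affine_kind == "none") NULL else
        register_affine(t2w[[i]], template, kind = config$affine_kind,
                        maxit = config$affine_maxit)
      reg <- register_nonlinear(t2w[[i]], template, init = init,
                                levels = config$demons_levels,
                                iterations = config$demons_iterations,
                                sigma_update = config$sigma_update,
                                sigma_total = config$sigma_total)
      regs[[i]] <- reg
      # smooth the unmasked map first: the field extends smoothly past the
      # brain boundary, and masking before smoothing would drag cortical
      # edge values toward zero
      lj <- log_jacobian(jacobian_determinant(reg$field))
      if (config$logj_smooth > 0)
        lj <- volume(gaussian_smooth3(lj$data,
                                      config$logj_smooth / lj$spacing),
                     spacing = lj$spacing, affine = lj$affine,
                     units = lj$units)
      lj$data[tmask$data <= 0] <- 0
      logj[[i]] <- lj
    }

    irr <- which(sel$group == "irradiated")
    say("timepoint %s: voxel statistics (%d vs %d)", tp, length(irr),
        length(ctrl))
    sig <- fwe_correct(logj[irr], logj[ctrl], tmask, alpha = config$alpha,
                       n_perm = config$n_perm, seed = config$seed,
                       stat = config$stat)
    clus <- label_clusters(sig, connectivity = config$connectivity)
    keep <- clus$clusters$n_voxels >= config$min_cluster_voxels
    clus$clusters <- clus$clusters[keep, , drop = FALSE]
    clus$members <- clus$members[keep]
    props <- cluster_proportions(clus, tmask)

    warped_atlas <- register_atlas(atlas$labels, atlas$reference, template,
                                   maxit = config$affine_maxit)
    overlap <- clusters_to_structures(clus, warped_atlas,
                                      naming = atlas$naming)

    # quantitative maps per subject, warped to template space
    say("timepoint %s: quantitative maps", tp)
    qmaps <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      dwi <- read_volume(file.path_abs(sel$dwi[i], cohort$dir))
      tens <- fit_dti(dwi, btab, mask = masks[[i]])
      sc <- dti_scalars(tens)
      pre <- read_volume(file.path_abs(sel$t2s_pre[i], cohort$dir))
      post <- read_volume(file.path_abs(sel$t2s_post[i], cohort$dir))
      cbv <- cbv_map(delta_r2star(pre, post, config$te), config$contrast)
      cbv$data[!is.finite(cbv$data)] <- 0
      w <- function(v) apply_transform(v, regs[[i]], target = template)
      qmaps[[i]] <- list(JD = logj[[i]], CBV = w(cbv), MD = w(sc$MD),
                         AD = w(sc$AD), RD = w(sc$RD))
    }

    # ROI = union of same-sign significant voxels (the DBM clusters)
    for (sgn in c(-1, 1)) {
      vox <- unlist(clus$members[clus$clusters$sign == sgn])
      if (length(vox) < config$min_cluster_voxels) next
      roi_name <- paste0("dbm_", tp, if (sgn < 0) "_neg" else "_pos")
      roi_masks[[roi_name]] <- list(timepoint = tp, sign = sgn, voxels = vox)
    }

    results[[tp]] <- list(template = template, mask = tmask, logj = logj,
                          registrations = regs, sigmask = sig,
                          clusters = clus, overlap = overlap,
                          proportions = props, qmaps = qmaps,
                          subjects = sel)
  }

  # study table: per subject x timepoint x ROI means of all parameters
  for (tp in tps) {
    res <- results[[tp]]
    for (i in seq_len(nrow(res$subjects))) {
      for (roi_name in names(roi_masks)) {
        vox <- roi_masks[[roi_name]]$voxels
        row <- data.frame(subject_id = res$subjects$subject_id[i],
                          group = res$subjects$group[i], timepoint = tp,
                          roi = roi_name, stringsAsFactors = FALSE)
        for (p in c("JD", "CBV", "MD", "AD", "RD"))
          row[[p]] <- as.numeric(extract_roi_means(res$qmaps[[i]][[p]], vox))
        study_rows <- rbind(study_rows, row)
      }
    }
  }

  anovas <- list()
  correlations <- list()
  if (!is.null(study_rows) && length(unique(study_rows$timepoint)) >= 2) {
    for (roi_name in unique(study_rows$roi)) {
      tab <- study_rows[study_rows$roi == roi_name, ]
      anovas[[roi_name]] <- lapply(
        stats::setNames(nm = c("JD", "CBV", "MD", "AD", "RD")),
        function(p) tryCatch(two_way_anova_lsd(tab, p),
                             error = function(e) conditionMessage(e)))
      correlations[[roi_name]] <- list(
        pooled = pearson_matrix(tab, vars = c("JD", "CBV", "MD", "AD", "RD")),
        anchored = tryCatch(
          pearson_matrix(study_wide_table(tab)[, -(1:2)]),
          error = function(e) conditionMessage(e)))
    }
  }

  out <- structure(list(results = results, study_table = study_rows,
                        anova = anovas, correlations = correlations,
                        roi_masks = roi_masks, config = config,
                        manifest = manifest),
                   class = "dbm_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    for (tp in tps) {
      cl <- results[[tp]]$clusters$clusters
      f <- file.path(out_dir, paste0("clusters_", tp, ".csv"))
      utils::write.csv(cl, f, row.names = FALSE)
      files <- c(files, f)
    }
    props <- do.call(rbind, lapply(tps, function(tp)
      data.frame(timepoint = tp, t(results[[tp]]$proportions))))
    f <- file.path(out_dir, "cluster_proportions.csv")
    utils::write.csv(props, f, row.names = FALSE)
    files <- c(files, f)
    if (!is.null(study_rows)) {
      f <- file.path(out_dir, "study_table.csv")
      utils::write.csv(study_rows, f, row.names = FALSE)
      files <- c(files, f)
    }
    manifest_add(manifest, "outputs",
                 params = list(seed = config$seed), files = files)
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  out
}

# Paths in metadata.csv may be absolute or cohort-relative.
file.path_abs <- function(p, dir) if (file.exists(p)) p else file.path(dir, basename(p))

#' @export
print.dbm_study <- function(x, ...) {
  cat("<dbm_study>\n")
  for (tp in names(x$results)) {
    r <- x$results[[tp]]
    pr <- r$proportions
    cat(sprintf("  %s: %d clusters (%.2f%% neg, %.2f%% pos of brain)\n",
                tp, nrow(r$clusters$clusters), pr["negative_pct"],
                pr["positive_pct"]))
    if (!is.null(r$overlap$majority) && nrow(r$overlap$majority))
      cat(sprintf("    largest cluster: %s (sign %+d, %.0f%% overlap)\n",
                  r$overlap$majority$majority_structure[1],
                  r$overlap$majority$sign[1],
                  100 * r$overlap$majority$majority_fraction[1]))
  }
  invisible(x)
}

#' @export
summary.dbm_study <- function(object, ...) {
  print(object)
  if (!is.null(object$study_table)) {
    cat("\nstudy table (head):\n")
    print(utils::head(object$study_table))
  }
  invisible(object)
}
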