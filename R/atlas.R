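#' Register a label atlas into template space
#'
#' Rigid (by default) registration of the atlas reference intensity volume
#' to the study template, then nearest-neighbour resampling of the label
#' map onto the template grid -- labels are never interpolated, so the
#' warped label set is a subset of the original.
#'
#' @param atlas_labels integer `morpho_volume` of structure labels.
#' @param atlas_ref intensity `morpho_volume` in atlas space.
#' @param template study template `morpho_volume`.
#' @param kind registration family, default `"rigid"`.
#' @param ... passed to [register_affine()].
#' @return label `morpho_volume` on the template grid (carries over any
#'   `names_table` attribute).
#' @export
register_atlas <- function(atlas_labels, atlas_ref, template,
                           kind = "rigid", ...) {
  stopifnot(is_volume(atlas_labels), is_volume(atlas_ref),
            is_volume(template))
  tf <- register_affine(atlas_ref, template, kind = kind, ...)
  res <- structure(list(affine = tf, field = NULL),
                   class = "registration_result")
  out <- apply_transform(atlas_labels, res, target = template,
                         interpolation = "nearest")
  attr(out, "names_table") <- attr(atlas_labels, "names_table")
  out
}

#' Name the structures underlying significant clusters
#'
#' For each cluster, tallies the atlas labels of its member voxels and
#' reports per-structure overlap fractions and the majority structure.
#'
#' @param clusters a `cluster_set` (template space).
#' @param labels label `morpho_volume` on the same grid.
#' @param naming data.frame with columns `label_id`, `name` (defaults to
#'   the `names_table` attribute of `labels`); ids absent from it are
#'   reported as `"unnamed:<id>"`.
#' @return an `atlas_overlap` object: `overlaps` (long data.frame: cluster,
#'   structure, voxels, fraction) and `majority` (one row per cluster).
#' @export
clusters_to_structures <- function(clusters, labels, naming = NULL) {
  stopifnot(inherits(clusters, "cluster_set"), is_volume(labels))
  if (!all(clusters$dim == grid_dim(labels)))
    stop("clusters and labels are not in the same space")
  if (is.null(naming)) naming <- attr(labels, "names_table")
  if (is.null(naming)) stop("no naming table available")
  name_of <- function(id) {
    hit <- naming$name[naming$label_id == id]
    if (length(hit)) hit else paste0("unnamed:", id)
  }
  overlaps <- NULL
  majority <- NULL
  for (i in seq_len(nrow(clusters$clusters))) {
    vox <- clusters$members[[i]]
    labs <- labels$data[vox]
    tab <- table(labs[labs > 0])
    if (length(tab) == 0) {
      majority <- rbind(majority, data.frame(
        cluster_id = clusters$clusters$cluster_id[i],
        sign = clusters$clusters$sign[i],
        majority_structure = NA_character_, majority_fraction = 0,
        stringsAsFactors = FALSE))
      next
    }
    ids <- as.integer(names(tab))
    fr <- as.integer(tab) / length(vox)
    ord <- order(-fr)
    overlaps <- rbind(overlaps, data.frame(
      cluster_id = clusters$clusters$cluster_id[i],
      sign = clusters$clusters$sign[i],
      structure = vapply(ids[ord], name_of, ""),
      overlap_voxels = as.integer(tab)[ord],
      overlap_fraction = fr[ord], stringsAsFactors = FALSE))
    majority <- rbind(majority, data.frame(
      cluster_id = clusters$clusters$cluster_id[i],
      sign = clusters$clusters$sign[i],
      majority_structure = name_of(ids[ord][1]),
      majority_fraction = fr[ord][1], stringsAsFactors = FALSE))
  }
  structure(list(overlaps = overlaps, majority = majority),
            class = "atlas_overlap")
}

#' @export
print.atlas_overlap <- function(x, ...) {
  cat("<atlas_overlap>\n")
  if (!is.null(x$majority)) print(x$majority)
  invisible(x)
}
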