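#' Jacobian determinant of a displacement field
#'
#' `J(x) = det(I + grad u(x))` with the displacement gradient taken by
#' spacing-aware central differences in world millimetres (one-sided at
#' boundary faces). `J > 1` marks local expansion of the subject relative
#' to the template, `J < 1` local contraction.
#'
#' @param field a `morpho_field` (template -> subject).
#' @return `morpho_volume` of determinants (unitless);
#'   `attr(, "n_nonpositive")` counts non-positive voxels.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "morpho_field"))
  J <- field_jacobian_data(field$data, field$spacing)
  out <- volume(J, spacing = field$spacing, affine = field$affine,
                units = "ratio")
  attr(out, "n_nonpositive") <- sum(J <= 0)
  out
}

#' Log-Jacobian map
#'
#' Natural-log transform of a Jacobian determinant map, the scale on which
#' deformation-based morphometry statistics are run: `logJ = 0` where the
#' field is identity, `> 0` for expansion, `< 0` for contraction, and the
#' measure is additive under composition of deformations.
#'
#' @param detmap `morpho_volume` from [jacobian_determinant()].
#' @param eps lower clamp applied before the log (clamped voxels counted).
#' @param mask optional binary `morpho_volume`; voxels outside are set 0.
#' @return `morpho_volume` of log-Jacobians (`units = "log-ratio"`);
#'   `attr(, "n_clamped")` counts clamped voxels.
#' @export
log_jacobian <- function(detmap, eps = 1e-6, mask = NULL) {
  stopifnot(is_volume(detmap))
  J <- detmap$data
  n_clamped <- sum(J < eps)
  logJ <- log(pmax(J, eps))
  if (!is.null(mask)) {
    stop_if_geometry_differs(detmap, mask)
    logJ[mask$data <= 0] <- 0
  }
  out <- volume(array(logJ, grid_dim(detmap)), spacing = detmap$spacing,
                affine = detmap$affine, units = "log-ratio")
  attr(out, "n_clamped") <- n_clamped
  out
}
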