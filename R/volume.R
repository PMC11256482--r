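#' 3D image volume with physical geometry
#'
#' The basic container of the pipeline: a scalar 3D array (or a 4D array for
#' multi-channel data such as diffusion series or displacement fields) plus
#' the voxel spacing in mm and a 4x4 voxel-to-world affine. All geometric
#' computation downstream is done in world millimetres through the affine;
#' voxel `(1,1,1)` maps to the affine's translation column (0-based index
#' convention in world space).
#'
#' @param data numeric 3D (or 4D) array.
#' @param spacing numeric length-3, mm per voxel along each axis; must be
#'   strictly positive.
#' @param affine 4x4 voxel-to-world matrix; default is `diag(spacing)` with
#'   origin at 0. Must be invertible.
#' @param units free-text unit tag (`"arbitrary"`, `"%"`, `"1/s"`,
#'   `"um^2/s"`, `"log-ratio"`, ...).
#' @return an object of class `morpho_volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                   units = "arbitrary") {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3D or 4D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be an invertible 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine,
                 units = units),
            class = "morpho_volume")
}

#' @export
print.morpho_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<morpho_volume> %s voxels, spacing %s mm, units '%s'\n",
              paste(d, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$units))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  intensity range [%.4g, %.4g]", rng[1], rng[2]))
  nna <- sum(!is.finite(x$data))
  if (nna > 0) cat(sprintf(", %d non-finite voxels", nna))
  cat("\n")
  invisible(x)
}

#' @export
dim.morpho_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "morpho_volume")

#' Spatial grid dimensions (first three axes) of a volume
#' @param vol a `morpho_volume`.
#' @return integer length-3.
#' @export
grid_dim <- function(vol) dim(vol$data)[1:3]

#' Test two volumes for matching voxel grid and world geometry
#' @param a,b `morpho_volume` objects.
#' @param tol numeric tolerance on spacing/affine entries.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  all(grid_dim(a) == grid_dim(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

stop_if_geometry_differs <- function(a, b) {
  if (!same_geometry(a, b))
    stop("volumes do not share grid/geometry")
  invisible(TRUE)
}

#' World coordinates (mm) of every voxel centre
#'
#' @param vol a `morpho_volume`.
#' @return n x 3 matrix of world coordinates in voxel-storage order
#'   (first axis fastest).
#' @export
voxel_world_coords <- function(vol) {
  d <- grid_dim(vol)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
  xyz1 <- cbind(ijk, 1) %*% t(vol$affine)
  xyz1[, 1:3, drop = FALSE]
}

#' Convert world coordinates to continuous 0-based voxel indices
#' @param vol a `morpho_volume`.
#' @param xyz n x 3 matrix of world mm.
#' @return n x 3 matrix of continuous voxel indices (0-based).
#' @export
world_to_voxel <- function(vol, xyz) {
  inv <- solve(vol$affine)
  out <- cbind(xyz, 1) %*% t(inv)
  out[, 1:3, drop = FALSE]
}

#' Sample a volume at world coordinates
#'
#' @param vol a 3D `morpho_volume`.
#' @param xyz n x 3 world coordinates (mm).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return numeric vector of sampled values (border replicated outside).
#' @export
sample_volume <- function(vol, xyz, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  v <- world_to_voxel(vol, xyz)
  d <- grid_dim(vol)
  if (interpolation == "linear")
    .interp3_trilinear(as.double(vol$data), as.integer(d),
                       v[, 1], v[, 2], v[, 3])
  else
    .interp3_nearest(as.double(vol$data), as.integer(d),
                     v[, 1], v[, 2], v[, 3])
}

#' Gaussian smoothing of a 3D array (separable, replicate border)
#'
#' @param arr 3D numeric array.
#' @param sigma standard deviation in voxels, scalar or length-3. Zero skips
#'   the corresponding axis.
#' @return smoothed array of the same dimensions.
#' @export
gaussian_smooth3 <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3)
  d <- dim(arr)
  out <- as.double(arr)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    out <- .conv_axis3(out, as.integer(d), k, ax - 1L)
  }
  array(out, d)
}

# Downsample a 3D array by integer factor (block mean); used by the
# multi-resolution registration pyramid.
downsample3 <- function(vol, factor) {
  if (factor == 1L) return(vol)
  d <- grid_dim(vol)
  nd <- pmax(1L, d %/% factor)
  arr <- gaussian_smooth3(vol$data, sigma = factor / 2)
  # sample at block centres (0-based voxel coords of the fine grid)
  gx <- (seq_len(nd[1]) - 1) * factor + (factor - 1) / 2
  gy <- (seq_len(nd[2]) - 1) * factor + (factor - 1) / 2
  gz <- (seq_len(nd[3]) - 1) * factor + (factor - 1) / 2
  co <- cbind(
    rep.int(gx, nd[2] * nd[3]),
    rep.int(rep(gy, each = nd[1]), nd[3]),
    rep(gz, each = nd[1] * nd[2])
  )
  vals <- .interp3_trilinear(as.double(arr), as.integer(d),
                             co[, 1], co[, 2], co[, 3])
  sp <- vol$spacing * factor
  aff <- vol$affine
  # new voxel index i maps to old index i*factor + (factor-1)/2
  M <- diag(c(rep(factor, 3), 1))
  M[1:3, 4] <- (factor - 1) / 2
  volume(array(vals, nd), spacing = sp, affine = aff %*% M,
         units = vol$units)
}
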