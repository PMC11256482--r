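#' Otsu threshold of an intensity sample
#'
#' Maximises between-class variance over a 256-bin histogram.
#'
#' @param x numeric vector of intensities.
#' @param nbins histogram bins.
#' @return threshold value; errors if the input is constant.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 0) stop("no threshold separates classes (constant image)")
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nbins)
  sigma_b[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  centers[which.max(sigma_b)]
}

#' Automatic brain mask
#'
#' Otsu threshold, largest 26-connected foreground component, morphological
#' closing with a ball of radius 2 voxels, then hole filling (background
#' components not touching the volume border become foreground). The result
#' is a single connected component by construction. Deterministic; a
#' user-supplied mask can be passed downstream instead wherever a mask
#' argument is accepted.
#'
#' @param vol a `morpho_volume` with bimodal foreground/background
#'   intensities.
#' @param closing_radius ball radius (voxels) of the closing step.
#' @return binary `morpho_volume` mask; `attr(, "provenance") = "auto"`.
#' @export
brain_mask <- function(vol, closing_radius = 2) {
  stopifnot(is_volume(vol))
  d <- grid_dim(vol)
  thr <- otsu_threshold(as.vector(vol$data))
  fg <- as.integer(vol$data > thr)
  lab <- .label_components3(fg, as.integer(d), 26L)
  if (max(lab) == 0) stop("no foreground voxels above threshold")
  sizes <- tabulate(lab[lab > 0])
  fg <- as.integer(lab == which.max(sizes))
  # closing: dilate then erode
  fg <- .morph3_ball(fg, as.integer(d), closing_radius, 1L)
  fg <- .morph3_ball(fg, as.integer(d), closing_radius, 0L)
  # hole filling: background components not reaching the border
  bg <- .label_components3(as.integer(fg == 0L), as.integer(d), 6L)
  bga <- array(bg, d)
  border_ids <- unique(c(bga[c(1, d[1]), , ], bga[, c(1, d[2]), ],
                         bga[, , c(1, d[3])]))
  border_ids <- border_ids[border_ids > 0]
  fg[bg > 0 & !(bg %in% border_ids)] <- 1L
  # keep the largest component again (closing cannot split, but be safe)
  lab <- .label_components3(fg, as.integer(d), 26L)
  sizes <- tabulate(lab[lab > 0])
  mask <- volume(array(as.double(lab == which.max(sizes)), d),
                 spacing = vol$spacing, affine = vol$affine, units = "binary")
  attr(mask, "provenance") <- "auto"
  mask
}

#' Whole-brain volume from a mask
#'
#' @param mask binary `morpho_volume`.
#' @return foreground voxel count times voxel volume, in mm^3.
#' @export
whole_brain_volume <- function(mask) {
  stopifnot(is_volume(mask))
  sum(mask$data > 0) * prod(mask$spacing)
}

#' Polynomial intensity-inhomogeneity correction
#'
#' Fits an order-2 (10-coefficient) 3D polynomial to the log-intensities
#' inside the mask by iteratively reweighted least squares (Huber weights,
#' so minority tissue classes do not leak into the fitted field), divides
#' the fitted multiplicative field out, and rescales so the masked median
#' is unchanged. Suited to the smooth, low-order bias fields of
#' surface-coil MRI.
#'
#' @param vol a `morpho_volume` with positive intensities inside the mask
#'   (non-positive voxels are clipped to the smallest positive masked value,
#'   with a warning).
#' @param mask binary `morpho_volume`.
#' @param order polynomial order (1 or 2).
#' @return bias-corrected `morpho_volume`; `attr(, "bias_field")` holds the
#'   fitted multiplicative field.
#' @export
bias_correct <- function(vol, mask, order = 2L) {
  stopifnot(is_volume(vol), is_volume(mask))
  stop_if_geometry_differs(vol, mask)
  m <- mask$data > 0
  vals <- vol$data
  if (any(vals[m] <= 0)) {
    minpos <- min(vals[m][vals[m] > 0])
    warning(sum(vals[m] <= 0), " non-positive masked voxels clipped to ",
            signif(minpos, 4))
    vals[m & vals <= 0] <- minpos
  }
  xyz <- voxel_world_coords(vol)
  ctr <- colMeans(xyz[m, , drop = FALSE])
  half <- pmax(apply(abs(sweep(xyz[m, , drop = FALSE], 2, ctr)), 2, max), 1e-9)
  nx <- sweep(sweep(xyz, 2, ctr), 2, half, "/")
  X <- cbind(1, nx)
  if (order >= 2)
    X <- cbind(X, nx^2, nx[, 1] * nx[, 2], nx[, 1] * nx[, 3],
               nx[, 2] * nx[, 3])
  Xm <- X[m, , drop = FALSE]
  ym <- log(vals[m])
  w <- rep(1, length(ym))
  for (it in 1:6) {
    beta <- qr.solve(Xm * sqrt(w), ym * sqrt(w))
    r <- ym - as.vector(Xm %*% beta)
    s <- stats::mad(r)
    if (s <= 0) break
    u <- r / (4.685 * s)                    # Tukey bisquare weights
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(w == 0)) { w <- rep(1, length(ym)); break }
  }
  logb <- as.vector(X %*% beta)
  logb <- logb - mean(logb[m])
  b <- array(exp(logb), grid_dim(vol))
  corrected <- vol$data / b
  med0 <- stats::median(vol$data[m])
  med1 <- stats::median(corrected[m])
  if (med1 > 0) corrected <- corrected * (med0 / med1)
  out <- volume(corrected, spacing = vol$spacing, affine = vol$affine,
                units = vol$units)
  attr(out, "bias_field") <- volume(b, spacing = vol$spacing,
                                    affine = vol$affine)
  out
}
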