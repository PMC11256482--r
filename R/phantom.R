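#' Specification of the synthetic brain phantom
#'
#' The phantom stands in for a rodent brain on a T2-weighted scan: an
#' ellipsoidal brain with a cortical shell, a deep-grey interior
#' ("striatum"), a white-matter band ("corpus callosum") and paired CSF
#' ventricles, each with its own mean intensity. Geometry is analytic so
#' every voxel's true class is known, which is what makes the downstream
#' registration, Jacobian and statistics stages testable.
#'
#' @param grid_shape voxels per axis.
#' @param spacing mm per voxel; the default mirrors a high-resolution rodent
#'   T2w protocol (in-plane 0.25 mm, 0.5 mm slices).
#' @param brain_axes ellipsoid semi-axes in mm.
#' @param intensities named vector of class mean intensities (arbitrary
#'   units): `cortex`, `striatum`, `corpus_callosum`, `ventricles`.
#' @param noise_sigma Rician noise scale, same units as `intensities`.
#' @param bias_amplitude peak deviation of the multiplicative bias field
#'   (0.2 means the field spans roughly 0.8--1.2).
#' @param rng_seed integer seed for noise/bias realisations.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         spacing = c(0.25, 0.25, 0.5),
                         brain_axes = c(5.5, 6.5, 9),
                         intensities = c(cortex = 100, striatum = 92,
                                         corpus_callosum = 70,
                                         ventricles = 180),
                         noise_sigma = 2,
                         bias_amplitude = 0.2,
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (any(brain_axes <= 0)) stop("degenerate geometry: brain semi-axes must be > 0")
  fov_half <- grid_shape * spacing / 2
  if (any(brain_axes >= fov_half))
    stop("grid too small to contain the brain geometry (semi-axes ",
         paste(brain_axes, collapse = "x"), " mm vs half-FOV ",
         paste(signif(fov_half, 3), collapse = "x"), " mm)")
  need <- c("cortex", "striatum", "corpus_callosum", "ventricles")
  if (!all(need %in% names(intensities)))
    stop("intensities must name: ", paste(need, collapse = ", "))
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 brain_axes = as.numeric(brain_axes),
                 intensities = intensities,
                 noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Label ids and names of the phantom tissue classes
#'
#' @return data.frame with `label_id`, `name`, `area_group` -- the naming
#'   table consumed by [clusters_to_structures()].
#' @export
phantom_label_names <- function() {
  data.frame(
    label_id = 1:4,
    name = c("cortex", "striatum", "corpus_callosum", "ventricles"),
    area_group = c("cortex", "deep_grey", "white_matter", "csf"),
    stringsAsFactors = FALSE
  )
}

# Analytic tissue-class predicate evaluated on world coordinates.
# Returns integer labels (0 background, see phantom_label_names()).
phantom_labels_at <- function(spec, xyz) {
  centre <- spec$grid_shape * spec$spacing / 2
  dx <- sweep(xyz, 2, centre)
  ax <- spec$brain_axes
  rho <- sqrt((dx[, 1] / ax[1])^2 + (dx[, 2] / ax[2])^2 + (dx[, 3] / ax[3])^2)
  lab <- integer(nrow(xyz))
  inside <- rho <= 1
  lab[inside] <- 2L                                   # striatum = interior bulk
  lab[inside & rho >= 0.58] <- 1L                     # cortex shell
  cc <- inside & rho < 0.54 &
    dx[, 3] >= 0.04 * ax[3] & dx[, 3] <= 0.40 * ax[3] # corpus-callosum band
  lab[cc] <- 3L
  # gyrus-like cortical thickening in the +x sector (the shell reaches
  # deeper there, as cortex does at a gyrus); also breaks the remaining
  # left/right symmetry
  gyrus <- inside & rho >= 0.42 &
    (dx[, 1] / ax[1]) / pmax(rho, 1e-9) > 0.82
  lab[gyrus] <- 1L
  for (s in c(-1, 1)) {                               # paired ventricles,
    sc <- if (s < 0) 1.2 else 0.85                    # left/right asymmetric
    vc <- c(s * 0.30 * ax[1], 0.08 * s * ax[2], -0.05 * ax[3])
    vr <- sqrt(((dx[, 1] - vc[1]) / (sc * 0.14 * ax[1]))^2 +
               ((dx[, 2] - vc[2]) / (sc * 0.34 * ax[2]))^2 +
               ((dx[, 3] - vc[3]) / (sc * 0.16 * ax[3]))^2)
    lab[inside & vr <= 1] <- 4L
  }
  lab
}

#' Generate the noise-free phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (noise-free intensity `morpho_volume`, class
#'   means exact) and `labels` (integer `morpho_volume` ground truth,
#'   `attr(, "names_table")` = [phantom_label_names()]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- volume(array(0, spec$grid_shape), spacing = spec$spacing)
  xyz <- voxel_world_coords(geom)
  lab <- phantom_labels_at(spec, xyz)
  lut <- c(0, spec$intensities[c("cortex", "striatum", "corpus_callosum",
                                 "ventricles")])
  vals <- lut[lab + 1L]
  vol <- volume(array(vals, spec$grid_shape), spacing = spec$spacing,
                units = "arbitrary")
  labels <- volume(array(as.double(lab), spec$grid_shape),
                   spacing = spec$spacing, units = "label")
  attr(labels, "names_table") <- phantom_label_names()
  list(volume = vol, labels = labels)
}

#' Focal Gaussian deformation specification
#'
#' One radial Gaussian "blob": displacement
#' `u(x) = a (x - c) exp(-||x - c||^2 / (2 sigma^2))` with
#' `a = volume_ratio^(1/3) - 1`, so the Jacobian determinant at the centre
#' is exactly `volume_ratio` (local expansion for ratio > 1, contraction
#' for ratio < 1).
#'
#' @param center physical centre (mm, length 3).
#' @param sigma Gaussian radius (mm), > 0.
#' @param volume_ratio target Jacobian determinant at the centre, > 0.
#' @return a `focal_deformation` list.
#' @export
focal_deformation <- function(center, sigma, volume_ratio) {
  if (volume_ratio <= 0) stop("volume_ratio must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(center = as.numeric(center), sigma = as.numeric(sigma),
                 volume_ratio = as.numeric(volume_ratio)),
            class = "focal_deformation")
}

#' Build a displacement field from focal deformation blobs
#'
#' Superposes the radial Gaussian blobs of each [focal_deformation()] on the
#' reference grid. Because the family is analytic, the exact Jacobian of
#' `Phi(x) = x + u(x)` is available in closed form and returned alongside
#' the sampled field.
#'
#' @param specs list of [focal_deformation()] (empty list gives the identity
#'   field).
#' @param grid a `morpho_volume` providing the reference geometry.
#' @return list: `field` (`morpho_field`), `jacobian(xyz)` (function
#'   evaluating the analytic Jacobian determinant at n x 3 world
#'   coordinates), `specs`.
#' @export
make_deformation <- function(specs, grid) {
  stopifnot(is_volume(grid))
  if (inherits(specs, "focal_deformation")) specs <- list(specs)
  for (s in specs) {
    if (!inherits(s, "focal_deformation")) stop("specs must be focal_deformation objects")
    centre_ok <- all(s$center >= 0 & s$center <= grid_dim(grid) * grid$spacing)
    if (!centre_ok) stop("blob centre lies outside the grid")
  }
  if (length(specs) >= 2) {
    for (i in seq_len(length(specs) - 1))
      for (j in seq(i + 1, length(specs))) {
        d <- sqrt(sum((specs[[i]]$center - specs[[j]]$center)^2))
        if (d < 3 * (specs[[i]]$sigma + specs[[j]]$sigma))
          warning("focal blobs ", i, " and ", j,
                  " overlap (centres closer than 3*(sigma_i+sigma_j)); ",
                  "centre Jacobians are no longer exact")
      }
  }
  d <- grid_dim(grid)
  xyz <- voxel_world_coords(grid)
  u <- matrix(0, nrow(xyz), 3)
  for (s in specs) {
    a <- s$volume_ratio^(1 / 3) - 1
    dx <- sweep(xyz, 2, s$center)
    g <- exp(-rowSums(dx^2) / (2 * s$sigma^2))
    u <- u + a * dx * g
  }
  field <- displacement_field(array(u, c(d, 3)), spacing = grid$spacing,
                              affine = grid$affine)
  jac <- function(pts) {
    pts <- matrix(pts, ncol = 3)
    out <- numeric(nrow(pts))
    for (t in seq_len(nrow(pts))) {
      G <- diag(3)
      for (s in specs) {
        a <- s$volume_ratio^(1 / 3) - 1
        dx <- pts[t, ] - s$center
        g <- exp(-sum(dx^2) / (2 * s$sigma^2))
        G <- G + a * g * diag(3) - (a * g / s$sigma^2) * (dx %o% dx)
      }
      out[t] <- det(G)
    }
    out
  }
  list(field = field, jacobian = jac, specs = specs)
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for `v` such that `(x + v) + u(x + v) = x`, i.e.
#' the displacement of `Phi^{-1}`. Converges rapidly for the smooth,
#' moderate fields used here.
#'
#' @param field a `morpho_field`.
#' @param iterations fixed-point iterations.
#' @return a `morpho_field` holding the inverse displacement.
#' @export
invert_displacement <- function(field, iterations = 25L) {
  d <- dim(field$data)[1:3]
  ref <- volume(array(0, d), spacing = field$spacing, affine = field$affine)
  xyz <- voxel_world_coords(ref)
  v <- matrix(0, nrow(xyz), 3)
  comp <- lapply(1:3, function(c) as.double(field$data[, , , c]))
  inv_aff <- solve(field$affine)
  for (it in seq_len(iterations)) {
    p <- xyz + v
    vox <- cbind(p, 1) %*% t(inv_aff)
    for (c in 1:3)
      v[, c] <- -.interp3_trilinear(comp[[c]], as.integer(d),
                                    vox[, 1], vox[, 2], vox[, 3])
  }
  displacement_field(array(v, c(d, 3)), spacing = field$spacing,
                     affine = field$affine)
}

#' Multiplicative intra-tissue texture
#'
#' Superposes smooth random fields at the given voxel scales as a
#' multiplicative modulation. Real T2w images carry anatomical texture that
#' makes deformation observable away from tissue boundaries; the class-mean
#' phantom does not, so the cohort generator applies this (deterministic,
#' shared across subjects -- it plays the role of common anatomy and
#' deforms with the tissue).
#'
#' @param vol a `morpho_volume`.
#' @param amplitudes peak modulation per scale component.
#' @param scales Gaussian correlation lengths in voxels.
#' @param seed RNG seed.
#' @return textured `morpho_volume`.
#' @export
add_texture <- function(vol, amplitudes = c(0.15, 0.15),
                        scales = c(1.5, 4), seed = 1L) {
  stopifnot(is_volume(vol), length(amplitudes) == length(scales))
  d <- grid_dim(vol)
  tex <- withr_seed(seed, {
    acc <- array(0, d)
    for (i in seq_along(scales)) {
      t <- gaussian_smooth3(array(stats::rnorm(prod(d)), d), scales[i])
      acc <- acc + amplitudes[i] * t / max(abs(t))
    }
    acc
  })
  volume(vol$data * (1 + tex), spacing = vol$spacing, affine = vol$affine,
         units = vol$units)
}

#' Smooth multiplicative bias field
#'
#' A random order-2 polynomial in normalised coordinates, rescaled so its
#' peak deviation from 1 equals `amplitude`; deterministic for a given seed.
#'
#' @param geometry a `morpho_volume` providing the grid.
#' @param amplitude peak deviation (0 gives a field of ones).
#' @param seed integer RNG seed.
#' @return a `morpho_volume` of multiplicative factors.
#' @export
make_bias_field <- function(geometry, amplitude, seed = 1L) {
  d <- grid_dim(geometry)
  if (amplitude == 0)
    return(volume(array(1, d), spacing = geometry$spacing,
                  affine = geometry$affine, units = "arbitrary"))
  xyz <- voxel_world_coords(geometry)
  ctr <- colMeans(xyz)
  half <- apply(xyz, 2, function(v) max(abs(v - mean(v))))
  nx <- sweep(sweep(xyz, 2, ctr), 2, half, "/")
  X <- cbind(nx, nx^2, nx[, 1] * nx[, 2], nx[, 1] * nx[, 3], nx[, 2] * nx[, 3])
  coef <- withr_seed(seed, stats::rnorm(ncol(X)))
  f <- as.vector(X %*% coef)
  f <- f - mean(f)
  f <- f / max(abs(f))
  volume(array(1 + amplitude * f, d), spacing = geometry$spacing,
         affine = geometry$affine, units = "arbitrary")
}

# Evaluate expr with a temporary RNG state seeded at `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Warp a volume and apply scanner-like degradation
#'
#' Resamples the volume through `Phi(x) = x + u(x)` by linear interpolation
#' (pull-back), multiplies by a smooth bias field, then applies Rician
#' magnitude corruption `sqrt((s + n1)^2 + n2^2)` with
#' `n1, n2 ~ N(0, noise_sigma)`.
#'
#' @param vol a `morpho_volume`.
#' @param field a `morpho_field` on the same grid, or `NULL` for identity.
#' @param spec a [phantom_spec()] supplying `noise_sigma`, `bias_amplitude`
#'   and `rng_seed`.
#' @param seed overrides `spec$rng_seed` (e.g. per subject).
#' @param interpolation passed to the resampling step.
#' @return degraded `morpho_volume`.
#' @export
warp_and_degrade <- function(vol, field = NULL, spec, seed = spec$rng_seed,
                             interpolation = "linear") {
  stopifnot(is_volume(vol))
  d <- grid_dim(vol)
  if (!is.null(field)) {
    if (!all(dim(field$data)[1:3] == d))
      stop("field and volume geometry differ")
    xyz <- voxel_world_coords(vol)
    u <- cbind(as.vector(field$data[, , , 1]), as.vector(field$data[, , , 2]),
               as.vector(field$data[, , , 3]))
    vals <- sample_volume(vol, xyz + u, interpolation = interpolation)
    out <- array(vals, d)
  } else {
    out <- vol$data
  }
  bias <- make_bias_field(vol, spec$bias_amplitude, seed = seed)
  out <- out * bias$data
  if (spec$noise_sigma > 0) {
    out <- withr_seed(seed + 1L, {
      n1 <- array(stats::rnorm(length(out), 0, spec$noise_sigma), d)
      n2 <- array(stats::rnorm(length(out), 0, spec$noise_sigma), d)
      sqrt((out + n1)^2 + n2^2)
    })
  }
  volume(out, spacing = vol$spacing, affine = vol$affine, units = vol$units)
}
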