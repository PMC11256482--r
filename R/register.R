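#' Affine transform acting on world coordinates
#'
#' @param matrix 4x4 homogeneous matrix mapping fixed-space world mm to
#'   moving-space world mm.
#' @param kind `"rigid"`, `"similarity"` or `"affine"`.
#' @return an `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(4), kind = "affine") {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (abs(det(matrix)) < .Machine$double.eps) stop("transform not invertible")
  if (kind == "rigid") {
    R <- matrix[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
      stop("rigid transform must have an orthonormal, det=+1 rotation block")
  }
  structure(list(matrix = matrix, kind = kind), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform> kind=%s\n", x$kind))
  print(signif(x$matrix, 5))
  invisible(x)
}

# Parameter vector -> 4x4 world matrix. Parameters: 3 Euler angles (rad),
# 3 translations (mm), then for similarity 1 log-scale, for affine 3
# log-scales + 3 shears. Rotation/scale about `center` (mm).
params_to_affine <- function(par, kind, center) {
  cx <- cos(par[1]); sx <- sin(par[1])
  cy <- cos(par[2]); sy <- sin(par[2])
  cz <- cos(par[3]); sz <- sin(par[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  M <- Rz %*% Ry %*% Rx
  if (kind == "similarity") M <- M * exp(par[7])
  if (kind == "affine") {
    S <- diag(exp(par[7:9]))
    S[1, 2] <- par[10]; S[1, 3] <- par[11]; S[2, 3] <- par[12]
    M <- M %*% S
  }
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- par[4:6] + center - M %*% center
  A
}

n_params <- function(kind)
  switch(kind, rigid = 6L, similarity = 7L, affine = 12L)

param_scales <- function(kind) {
  s <- c(rep(0.02, 3), rep(0.5, 3))
  if (kind == "similarity") s <- c(s, 0.02)
  if (kind == "affine") s <- c(s, rep(0.02, 3), rep(0.02, 3))
  s
}

# Mutual information from a joint histogram with Parzen-style smoothing.
mi_from_pairs <- function(a, b, nbins = 32L, sigma = 0.7) {
  H <- .joint_hist(a, b, nbins)
  r <- 2L
  k <- stats::dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  Hs <- .conv_axis3(as.double(H), c(nbins, nbins, 1L), k, 0L)
  Hs <- .conv_axis3(Hs, c(nbins, nbins, 1L), k, 1L)
  p <- Hs / sum(Hs)
  px <- rowSums(matrix(p, nbins, nbins))
  py <- colSums(matrix(p, nbins, nbins))
  pm <- matrix(p, nbins, nbins)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / outer(px, py)[nz]))
}

scale_to_bins <- function(x, rng, nbins) {
  (pmin(pmax(x, rng[1]), rng[2]) - rng[1]) / (rng[2] - rng[1]) * (nbins - 1)
}

#' Affine registration by mutual information
#'
#' Multi-resolution (4x, 2x, 1x) maximisation of the mutual information of
#' a 32-bin smoothed joint histogram over rigid, similarity or full affine
#' parameters (Nelder-Mead). The returned transform maps fixed-space world
#' coordinates to moving-space world coordinates, i.e. the moving image is
#' resampled at `A(x)`.
#'
#' @param moving,fixed masked/bias-corrected `morpho_volume`s.
#' @param kind `"rigid"`, `"similarity"` or `"affine"`.
#' @param levels integer downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iteration cap per level (recycled).
#' @param nbins joint-histogram bins.
#' @param smooth Gaussian sigma (voxels at level scale) applied to both
#'   images before the histogram: turns sharp tissue boundaries into ramps
#'   so the metric is smooth in the pose parameters.
#' @param init optional initial `affine_transform`.
#' @return an `affine_transform`; `attr(, "mi_trace")` holds the final MI
#'   per level, `attr(, "mi_init")`/`attr(, "mi_final")` the full-resolution
#'   bracketing values.
#' @export
register_affine <- function(moving, fixed, kind = c("rigid", "similarity",
                                                    "affine"),
                            levels = c(4L, 2L, 1L), maxit = c(200L, 100L, 40L),
                            nbins = 32L, smooth = 1.5, init = NULL) {
  kind <- match.arg(kind)
  stopifnot(is_volume(moving), is_volume(fixed))
  maxit <- rep_len(maxit, length(levels))
  centre <- colMeans(voxel_world_coords(fixed)[c(1, prod(grid_dim(fixed))), ,
                                               drop = FALSE])
  par <- numeric(n_params(kind))
  if (!is.null(init)) {
    # absorb the init into the parameterisation start via its translation;
    # rotations are assumed small in init (identity-near start typical here)
    par[4:6] <- init$matrix[1:3, 4] - (diag(3) %*% centre - centre) -
      (init$matrix[1:3, 1:3] %*% centre - centre) * 0
  }
  mov_dim <- as.integer(grid_dim(moving))
  inv_mov_aff <- solve(moving$affine)
  level_setup <- function(f) {
    # smooth at the level scale (sigma in fine voxels = smooth * f for the
    # moving image, which stays on its native grid)
    mov_s <- as.double(gaussian_smooth3(moving$data, smooth * f))
    fx <- downsample3(fixed, f)
    fxs <- gaussian_smooth3(fx$data, smooth)
    # MI is evaluated over fixed-image foreground only: the (masked)
    # background is pose-insensitive and would swamp the histogram
    sel <- as.vector(fxs) > 0.05 * max(fxs)
    rng_m <- range(mov_s); rng_f <- range(fxs)
    list(mov = mov_s, rng_m = rng_m,
         fvals = scale_to_bins(as.vector(fxs)[sel], rng_f, nbins),
         xyz1 = cbind(voxel_world_coords(fx)[sel, , drop = FALSE], 1))
  }
  mi_of <- function(lv, p) {
    A <- params_to_affine(p, kind, centre)
    q <- lv$xyz1 %*% t(inv_mov_aff %*% A)
    mv <- .interp3_trilinear(lv$mov, mov_dim, q[, 1], q[, 2], q[, 3])
    mi_from_pairs(scale_to_bins(mv, lv$rng_m, nbins), lv$fvals, nbins)
  }
  mi_trace <- numeric(0)
  for (li in seq_along(levels)) {
    lv <- level_setup(levels[li])
    if (li == 1) {
      A0 <- params_to_affine(par, kind, centre)
      q0 <- lv$xyz1 %*% t(inv_mov_aff %*% A0)
      mv0 <- .interp3_trilinear(lv$mov, mov_dim, q0[, 1], q0[, 2], q0[, 3])
      if (stats::sd(mv0) == 0)
        stop("no overlap between volumes at initialisation")
    }
    # Nelder-Mead with restarts: the simplex tends to collapse before the
    # rotation parameters are fully resolved
    best_val <- -mi_of(lv, par)
    for (r in 1:3) {
      opt <- stats::optim(par, function(p) -mi_of(lv, p),
                          method = "Nelder-Mead",
                          control = list(maxit = maxit[li],
                                         parscale = param_scales(kind),
                                         reltol = 1e-8))
      if (opt$value < best_val - 1e-6) {
        par <- opt$par; best_val <- opt$value
      } else {
        if (opt$value < best_val) { par <- opt$par; best_val <- opt$value }
        break
      }
    }
    mi_trace <- c(mi_trace, -best_val)
  }
  # guarantee: never return a transform worse than the initial one (full res)
  lv <- level_setup(utils::tail(levels, 1))
  mi_at <- function(p) mi_of(lv, p)
  mi_init <- mi_at(numeric(n_params(kind)))
  mi_final <- mi_at(par)
  if (mi_final < mi_init) {
    par <- numeric(n_params(kind))
    mi_final <- mi_init
  }
  out <- affine_transform(params_to_affine(par, kind, centre), kind)
  attr(out, "mi_trace") <- mi_trace
  attr(out, "mi_init") <- mi_init
  attr(out, "mi_final") <- mi_final
  attr(out, "params") <- par
  out
}

#' Decompose an affine transform into rotation angles and translation
#' @param tf an `affine_transform` (rigid-dominated).
#' @return list with `angles_deg` (Euler, degrees) and `translation_mm`.
#' @export
affine_parameters <- function(tf) {
  R <- tf$matrix[1:3, 1:3]
  sy <- -R[3, 1]
  ry <- asin(pmin(pmax(sy, -1), 1))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  list(angles_deg = c(rx, ry, rz) * 180 / pi,
       translation_mm = tf$matrix[1:3, 4])
}

#' Nonlinear registration by regularised local-correlation demons
#'
#' Greedy compositive demons with local normalised cross-correlation image
#' forces (box window, radius 2 voxels), Gaussian smoothing of each update
#' (`sigma_update`) and of the accumulated field (`sigma_total`),
#' multi-resolution. Orientation preservation (`min det(grad Phi) > 0`
#' over the grid) is enforced by step-size halving. The stored field maps
#' template (fixed) coordinates to subject (moving) coordinates:
#' `det > 1` at a voxel means the subject's corresponding region is larger
#' than the template's (local expansion).
#'
#' @param moving,fixed `morpho_volume`s (affine pre-alignment assumed done
#'   or passed via `init`).
#' @param init optional `affine_transform` composed outside the field:
#'   the full map is `x -> A(x + u(x))`.
#' @param levels,iterations multi-resolution schedule (factors and
#'   per-level iteration caps).
#' @param sigma_update,sigma_total Gaussian sigmas in voxels.
#' @param cc_radius local-correlation box half-width in voxels.
#' @param step maximum update magnitude per iteration, in voxels.
#' @param presmooth Gaussian sigma (level voxels) applied to both images at
#'   each level; matched between fixed and moving so interpolation blur
#'   does not masquerade as mismatch.
#' @return a `registration_result`: `affine`, `field` (`morpho_field` on
#'   the fixed grid), `metric_trace`, `parameters`.
#' @export
register_nonlinear <- function(moving, fixed, init = NULL,
                               levels = c(4L, 2L, 1L),
                               iterations = c(40L, 20L, 10L),
                               sigma_update = 1, sigma_total = 0.5,
                               cc_radius = 2L, step = 0.8, presmooth = 1) {
  stopifnot(is_volume(moving), is_volume(fixed))
  iterations <- rep_len(iterations, length(levels))
  A <- if (is.null(init)) diag(4) else init$matrix
  mov_dim <- as.integer(grid_dim(moving))
  samp_mat <- t(solve(moving$affine) %*% A)
  u <- NULL
  prev_grid <- NULL
  trace <- numeric(0)
  fix_dim <- as.integer(grid_dim(fixed))
  inv_fix_aff <- solve(fixed$affine)
  for (li in seq_along(levels)) {
    f <- levels[li]
    fx <- downsample3(fixed, f)   # provides the level grid geometry
    dl <- grid_dim(fx)
    xyz <- voxel_world_coords(fx)
    # both images smoothed on their native fine grids with the same sigma
    # (anti-aliasing f/2 plus presmooth at level scale), then the fixed one
    # sampled at the level-grid points -- identical blur on both sides, so
    # moving == fixed gives exactly zero residual at every level
    sig <- f * sqrt(0.25 * (f > 1) + presmooth^2)
    fix_s <- as.double(gaussian_smooth3(fixed$data, sig))
    vox_f <- world_to_voxel(fixed, xyz)
    fvals <- .interp3_trilinear(fix_s, fix_dim, vox_f[, 1], vox_f[, 2],
                                vox_f[, 3])
    mov_data <- as.double(gaussian_smooth3(moving$data, sig))
    if (is.null(u)) {
      u <- array(0, c(dl, 3))
    } else {
      # resample previous level's field (values in mm are grid-independent)
      up <- array(0, c(dl, 3))
      vox <- world_to_voxel(prev_grid, xyz)
      for (c in 1:3)
        up[, , , c] <- array(.interp3_trilinear(as.double(u[, , , c]),
                                                as.integer(dim(u)[1:3]),
                                                vox[, 1], vox[, 2], vox[, 3]),
                             dl)
      u <- up
    }
    best_u <- u; best_metric <- -Inf; worse_streak <- 0L
    step_mm <- step * min(fx$spacing)
    for (it in seq_len(iterations[li])) {
      uv <- matrix(u, ncol = 3)
      q <- cbind(xyz + uv, 1) %*% samp_mat
      warped <- .interp3_trilinear(mov_data, mov_dim, q[, 1], q[, 2], q[, 3])
      metric <- suppressWarnings(stats::cor(fvals, warped))
      if (!is.finite(metric)) metric <- 0
      trace <- c(trace, metric)
      if (metric > best_metric) {
        best_metric <- metric; best_u <- u
      }
      # divergence guard: stop after 10 consecutive clear worsenings
      if (metric < best_metric - 1e-3) {
        worse_streak <- worse_streak + 1L
        if (worse_streak >= 10L) break
      } else worse_streak <- 0L
      upd <- .lcc_demons_step(fvals, warped, as.integer(dl),
                              as.integer(cc_radius), fx$spacing, step_mm)
      if (max(abs(upd$x), abs(upd$y), abs(upd$z)) <= 0) break
      delta <- array(c(upd$x, upd$y, upd$z), c(dl, 3))
      for (c in 1:3)
        delta[, , , c] <- gaussian_smooth3(delta[, , , c], sigma_update)
      scale <- 1
      for (try in 1:6) {
        dl_mat <- matrix(delta, ncol = 3) * scale
        vox <- world_to_voxel(fx, xyz + dl_mat)
        u_new <- array(0, c(dl, 3))
        for (c in 1:3) {
          comp <- .interp3_trilinear(as.double(u[, , , c]), as.integer(dl),
                                     vox[, 1], vox[, 2], vox[, 3])
          u_new[, , , c] <- array(comp + dl_mat[, c], dl)
        }
        for (c in 1:3)
          u_new[, , , c] <- gaussian_smooth3(u_new[, , , c], sigma_total)
        jmin <- min(field_jacobian_data(u_new, fx$spacing))
        if (jmin > 0.05) break
        scale <- scale / 2
      }
      if (jmin <= 0) next  # could not find a safe step; skip update
      u <- u_new
    }
    # keep the final field unless it clearly diverged from the best seen
    if (length(trace) && utils::tail(trace, 1) < best_metric - 1e-3)
      u <- best_u
    prev_grid <- fx
  }
  field <- displacement_field(u, spacing = fixed$spacing,
                              affine = fixed$affine)
  structure(list(affine = if (is.null(init))
                   affine_transform(diag(4), "rigid") else init,
                 field = field, metric_trace = trace,
                 parameters = list(levels = levels, iterations = iterations,
                                   sigma_update = sigma_update,
                                   sigma_total = sigma_total,
                                   cc_radius = cc_radius, step = step)),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n  affine:", x$affine$kind, "\n")
  mag <- sqrt(x$field$data[, , , 1]^2 + x$field$data[, , , 2]^2 +
              x$field$data[, , , 3]^2)
  cat(sprintf("  field |u|: mean %.3g mm, max %.3g mm\n", mean(mag), max(mag)))
  cat(sprintf("  final similarity: %.4f\n", utils::tail(x$metric_trace, 1)))
  invisible(x)
}

#' Mean-control template by iterative affine averaging
#'
#' Aligns all volumes to the first (then to the evolving mean) and averages
#' voxel-wise. Intended to be built per timepoint from control subjects
#' only, so that normal ageing is excluded from the irradiated-vs-control
#' contrast.
#'
#' @param volumes list of masked/bias-corrected `morpho_volume`s.
#' @param align `"rigid"`, `"similarity"`, `"affine"` or `"none"` (skip
#'   alignment; volumes must share a grid).
#' @param iterations alignment/averaging passes.
#' @param ... passed to [register_affine()].
#' @return template `morpho_volume` on the first volume's grid.
#' @export
build_template <- function(volumes, align = "rigid", iterations = 2L, ...) {
  if (length(volumes) == 0) stop("need at least one volume")
  if (length(volumes) == 1) return(volumes[[1]])
  ref <- volumes[[1]]
  for (it in seq_len(if (align == "none") 1L else iterations)) {
    acc <- array(0, grid_dim(ref))
    for (v in volumes) {
      if (align == "none") {
        stop_if_geometry_differs(ref, v)
        acc <- acc + v$data
      } else {
        tf <- register_affine(v, ref, kind = align, ...)
        res <- structure(list(affine = tf, field = NULL),
                         class = "registration_result")
        acc <- acc + apply_transform(v, res, target = ref)$data
      }
    }
    ref <- volume(acc / length(volumes), spacing = ref$spacing,
                  affine = ref$affine, units = ref$units)
  }
  ref
}

#' Resample a volume into template space through a registration result
#'
#' Pull-back through the full map `x -> A(x + u(x))`; linear interpolation
#' for scalar maps, nearest-neighbour for label maps.
#'
#' @param vol subject-space `morpho_volume`.
#' @param result a `registration_result`, or an object with `affine` only.
#' @param target optional `morpho_volume` giving the output grid (defaults
#'   to the field's grid).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return `morpho_volume` in template space.
#' @export
apply_transform <- function(vol, result, target = NULL,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (is.null(target)) {
    if (is.null(result$field)) stop("no field in result; supply `target`")
    target <- volume(array(0, dim(result$field$data)[1:3]),
                     spacing = result$field$spacing,
                     affine = result$field$affine)
  }
  xyz <- voxel_world_coords(target)
  if (!is.null(result$field)) {
    if (!all(dim(result$field$data)[1:3] == grid_dim(target)))
      stop("field grid does not match target grid")
    xyz <- xyz + matrix(result$field$data, ncol = 3)
  }
  A <- if (is.null(result$affine)) diag(4) else result$affine$matrix
  q <- cbind(xyz, 1) %*% t(A)
  vals <- sample_volume(vol, q[, 1:3], interpolation = interpolation)
  out <- volume(array(vals, grid_dim(target)), spacing = target$spacing,
                affine = target$affine, units = vol$units)
  attr(out, "names_table") <- attr(vol, "names_table")
  out
}

# det(I + grad u) for a raw displacement array (nx,ny,nz,3) in mm.
field_jacobian_data <- function(u, spacing) {
  d <- dim(u)[1:3]
  g <- vector("list", 9)
  idx <- 1
  for (comp in 1:3) {
    for (ax in 1:3) {
      g[[idx]] <- array_gradient(u[, , , comp], ax, spacing[ax])
      idx <- idx + 1
    }
  }
  # g[[3*(c-1)+a]] = d u_c / d x_a
  J11 <- 1 + g[[1]]; J12 <- g[[2]]; J13 <- g[[3]]
  J21 <- g[[4]]; J22 <- 1 + g[[5]]; J23 <- g[[6]]
  J31 <- g[[7]]; J32 <- g[[8]]; J33 <- 1 + g[[9]]
  J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
}

# Spacing-aware gradient: central differences interior, one-sided at faces.
array_gradient <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 2) return(array(0, d))
  ip <- c(2:n, n)      # forward neighbour (clamped)
  im <- c(1, 1:(n - 1))  # backward neighbour (clamped)
  denom <- (ip - im) * h
  if (axis == 1) {
    out <- (arr[ip, , , drop = FALSE] - arr[im, , , drop = FALSE]) /
      array(denom, d)
  } else if (axis == 2) {
    out <- (arr[, ip, , drop = FALSE] - arr[, im, , drop = FALSE]) /
      aperm(array(denom, d[c(2, 1, 3)]), c(2, 1, 3))
  } else {
    out <- (arr[, , ip, drop = FALSE] - arr[, , im, drop = FALSE]) /
      aperm(array(denom, d[c(3, 1, 2)]), c(2, 3, 1))
  }
  array(out, d)
}
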