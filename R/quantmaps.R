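#' Log-linear diffusion tensor fit
#'
#' Ordinary least squares on `ln S = ln S0 - b g' D g` per voxel over the
#' six unique tensor elements plus intercept -- the standard deterministic
#' estimator, exact on noise-free data (the design is identifiable with at
#' least 6 directions plus a b0). Eigenvalues are sorted descending; voxels with
#' negative eigenvalues are flagged, not clipped.
#'
#' @param dwi 4D `morpho_volume` `(nx, ny, nz, m)`.
#' @param protocol a [dwi_protocol()] (or list with `bvals`, `bvecs`).
#' @param mask binary `morpho_volume`; voxels with non-positive signals are
#'   excluded and flagged.
#' @return a `morpho_tensormap` with `evals` `(nx,ny,nz,3)`, `evec1`
#'   `(nx,ny,nz,3)`, `s0`, `mask` (fitted voxels) and counts
#'   `n_negative_evals`, `n_excluded`.
#' @export
fit_dti <- function(dwi, protocol, mask = NULL) {
  stopifnot(is_volume(dwi))
  d <- dim(dwi$data)
  if (length(d) != 4L) stop("dwi must be a 4D volume")
  m <- d[4]
  bv <- protocol$bvals; g <- protocol$bvecs
  if (length(bv) != m) stop("protocol has ", length(bv),
                            " measurements but dwi has ", m)
  if (m < 7L) stop("need at least 7 measurements (6 directions + b0)")
  X <- cbind(1, -bv * g[, 1]^2, -bv * g[, 2]^2, -bv * g[, 3]^2,
             -2 * bv * g[, 1] * g[, 2], -2 * bv * g[, 1] * g[, 3],
             -2 * bv * g[, 2] * g[, 3])
  if (qr(X)$rank < 7L) stop("rank-deficient design: directions do not span the tensor space")
  dim3 <- d[1:3]
  nv <- prod(dim3)
  S <- matrix(dwi$data, nv, m)
  sel <- if (is.null(mask)) rep(TRUE, nv) else as.vector(mask$data > 0)
  pos <- rowSums(S > 0) == m
  n_excluded <- sum(sel & !pos)
  fitted <- sel & pos
  beta <- matrix(0, 7, nv)
  if (any(fitted)) {
    lnS <- t(log(S[fitted, , drop = FALSE]))
    beta[, fitted] <- qr.solve(X, lnS)
  }
  t6 <- array(t(beta[2:7, ]), c(dim3, 6))
  e <- .eig3_sym(t(beta[2:7, , drop = FALSE]))
  evals <- array(e$values, c(dim3, 3))
  evec1 <- array(e$vector, c(dim3, 3))
  neg <- rowSums(matrix(e$values, nv, 3)[fitted, , drop = FALSE] < 0) > 0
  s0 <- volume(array(exp(beta[1, ]), dim3), spacing = dwi$spacing,
               affine = dwi$affine)
  out <- tensor_map(t6, spacing = dwi$spacing, affine = dwi$affine, s0 = s0)
  out$evals <- evals
  out$evec1 <- evec1
  out$mask <- array(fitted, dim3)
  out$n_negative_evals <- sum(neg)
  out$n_excluded <- n_excluded
  out
}

#' Diffusion scalar maps: MD, AD, RD
#'
#' Mean diffusivity `(l1+l2+l3)/3`, axial `l1`, radial `(l2+l3)/2`,
#' exported in um^2/s (internal tensors are mm^2/s; 1 mm^2/s = 1e6 um^2/s,
#' so 0.7e-3 mm^2/s -> 700 um^2/s, the scale usual in rodent reports).
#'
#' @param tensors a `morpho_tensormap` with eigenvalues (from [fit_dti()],
#'   or computed here if absent).
#' @return list of `MD`, `AD`, `RD` `morpho_volume`s (um^2/s).
#' @export
dti_scalars <- function(tensors) {
  stopifnot(inherits(tensors, "morpho_tensormap"))
  d <- dim(tensors$tensor)[1:3]
  if (is.null(tensors$evals)) {
    nv <- prod(d)
    e <- .eig3_sym(matrix(tensors$tensor, nv, 6))
    tensors$evals <- array(e$values, c(d, 3))
  }
  l1 <- tensors$evals[, , , 1]; l2 <- tensors$evals[, , , 2]
  l3 <- tensors$evals[, , , 3]
  mk <- function(x) volume(array(x * 1e6, d), spacing = tensors$spacing,
                           affine = tensors$affine, units = "um^2/s")
  list(MD = mk((l1 + l2 + l3) / 3), AD = mk(l1), RD = mk((l2 + l3) / 2))
}

#' Delta-R2* map from a pre/post-contrast T2* pair
#'
#' `DeltaR2* = ln(S_pre / S_post) / TE` per voxel (1/s). Voxels with
#' non-positive signal in either image are set NA and counted; voxels with
#' `S_post >= S_pre` produce `<= 0` and are flagged (not removed).
#'
#' @param pre,post `morpho_volume`s sharing a grid.
#' @param te echo time in seconds (> 0).
#' @return `morpho_volume` in 1/s; attributes `n_nonpositive_signal`,
#'   `n_nonpositive_dr2s`.
#' @export
delta_r2star <- function(pre, post, te) {
  stopifnot(is_volume(pre), is_volume(post))
  stop_if_geometry_differs(pre, post)
  if (te <= 0) stop("te must be > 0")
  bad <- pre$data <= 0 | post$data <= 0
  dr <- log(pre$data / post$data) / te
  dr[bad] <- NA_real_
  out <- volume(array(dr, grid_dim(pre)), spacing = pre$spacing,
                affine = pre$affine, units = "1/s")
  attr(out, "n_nonpositive_signal") <- sum(bad)
  attr(out, "n_nonpositive_dr2s") <- sum(dr <= 0, na.rm = TRUE)
  out
}

#' Steady-state cerebral blood volume map
#'
#' `CBV(%) = 100 * (3 / (4 pi)) * DeltaR2* / (gamma * delta_chi * B0)` --
#' the steady-state susceptibility-contrast estimator; CBV is the blood
#' volume fraction in ml blood per 100 ml tissue. Negative values (noise)
#' are flagged, never silently clipped.
#'
#' @param dr2s `morpho_volume` from [delta_r2star()].
#' @param protocol a [contrast_protocol()].
#' @return `morpho_volume` in %; attribute `n_negative`.
#' @export
cbv_map <- function(dr2s, protocol) {
  stopifnot(is_volume(dr2s), inherits(protocol, "contrast_protocol"))
  if (protocol$gamma_dchi_b0 == 0) stop("gamma * delta_chi * B0 must be nonzero")
  cbv <- 100 * (3 / (4 * pi)) * dr2s$data / protocol$gamma_dchi_b0
  out <- volume(array(cbv, grid_dim(dr2s)), spacing = dr2s$spacing,
                affine = dr2s$affine, units = "%")
  attr(out, "n_negative") <- sum(cbv < 0, na.rm = TRUE)
  out
}
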