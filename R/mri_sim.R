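#' Diffusion acquisition protocol
#'
#' Two-shell protocol in the usual rodent DTI configuration: one (or more)
#' b = 0 s/mm^2 reference and a shell of diffusion-sensitising directions.
#' Default: 30 unit directions at b = 1000 s/mm^2 (deterministic Fibonacci
#' hemisphere) plus a single b0.
#'
#' @param n_directions number of diffusion directions.
#' @param bvalue shell b-value in s/mm^2.
#' @param n_b0 number of b = 0 measurements.
#' @param s0 baseline (b = 0) signal.
#' @param te,tr echo/repetition time in seconds (informational).
#' @return a `dwi_protocol` with `bvals` (length m) and `bvecs` (m x 3,
#'   unit-norm for b > 0).
#' @export
dwi_protocol <- function(n_directions = 30L, bvalue = 1000, n_b0 = 1L,
                         s0 = 1000, te = 0.037, tr = 2.2) {
  dirs <- fibonacci_directions(n_directions)
  bvals <- c(rep(0, n_b0), rep(bvalue, n_directions))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  if (length(bvals) < 7L)
    stop("tensor fit needs at least 6 directions plus a b0 (7 measurements)")
  structure(list(bvals = bvals, bvecs = bvecs, s0 = s0, te = te, tr = tr),
            class = "dwi_protocol")
}

#' Deterministic near-uniform unit directions (Fibonacci hemisphere)
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  z <- i / n                      # upper hemisphere: antipodal pairs redundant
  theta <- 2 * pi * i / phi
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Diffusion tensor map container
#'
#' @param tensor 4D array `(nx, ny, nz, 6)` of unique tensor elements in
#'   the order xx, yy, zz, xy, xz, yz (mm^2/s).
#' @param spacing,affine grid geometry.
#' @param s0 optional baseline-signal `morpho_volume`.
#' @return a `morpho_tensormap`.
#' @export
tensor_map <- function(tensor, spacing = c(1, 1, 1), affine = NULL,
                       s0 = NULL) {
  if (length(dim(tensor)) == 5L) {
    # full 3x3 per voxel: require symmetry, then compress
    if (!all(dim(tensor)[4:5] == c(3, 3)))
      stop("5D tensor input must be (nx, ny, nz, 3, 3)")
    asym <- max(abs(tensor[, , , 1, 2] - tensor[, , , 2, 1]),
                abs(tensor[, , , 1, 3] - tensor[, , , 3, 1]),
                abs(tensor[, , , 2, 3] - tensor[, , , 3, 2]))
    if (asym > 1e-10) stop("tensor input is not symmetric")
    d <- dim(tensor)[1:3]
    tensor <- array(c(tensor[, , , 1, 1], tensor[, , , 2, 2],
                      tensor[, , , 3, 3], tensor[, , , 1, 2],
                      tensor[, , , 1, 3], tensor[, , , 2, 3]), c(d, 6))
  }
  if (length(dim(tensor)) != 4L || dim(tensor)[4] != 6L)
    stop("tensor must be (nx, ny, nz, 6)")
  v <- volume(tensor, spacing = spacing, affine = affine, units = "mm^2/s")
  structure(list(tensor = v$data, spacing = v$spacing, affine = v$affine,
                 s0 = s0),
            class = "morpho_tensormap")
}

#' @export
print.morpho_tensormap <- function(x, ...) {
  d <- dim(x$tensor)
  md <- (x$tensor[, , , 1] + x$tensor[, , , 2] + x$tensor[, , , 3]) / 3
  cat(sprintf("<morpho_tensormap> %s grid, MD range [%.3g, %.3g] mm^2/s\n",
              paste(d[1:3], collapse = "x"), min(md), max(md)))
  invisible(x)
}

# g' D g for rows of bvecs against the 6-element tensor columns (V x 6).
tensor_quadform <- function(t6, g) {
  t6[, 1] * g[1]^2 + t6[, 2] * g[2]^2 + t6[, 3] * g[3]^2 +
    2 * (t6[, 4] * g[1] * g[2] + t6[, 5] * g[1] * g[3] +
         t6[, 6] * g[2] * g[3])
}

#' Simulate a diffusion-weighted series from a tensor map
#'
#' Mono-exponential tensor signal model `S(g, b) = s0 exp(-b g' D g)` per
#' voxel and measurement; optional Rician corruption.
#'
#' @param tensors a [tensor_map()] (or a 5D `(..,3,3)` array, which is
#'   checked for symmetry).
#' @param protocol a [dwi_protocol()].
#' @param noise_sigma Rician noise SD in signal units (0 = noise-free).
#' @param seed RNG seed used when `noise_sigma > 0`.
#' @return 4D `morpho_volume` `(nx, ny, nz, m)` of signals.
#' @export
simulate_dwi <- function(tensors, protocol, noise_sigma = 0, seed = 1L) {
  if (!inherits(tensors, "morpho_tensormap"))
    tensors <- tensor_map(tensors)
  stopifnot(inherits(protocol, "dwi_protocol"))
  d <- dim(tensors$tensor)[1:3]
  nv <- prod(d)
  t6 <- matrix(tensors$tensor, nv, 6)
  m <- length(protocol$bvals)
  S <- matrix(0, nv, m)
  for (q in seq_len(m)) {
    qf <- tensor_quadform(t6, protocol$bvecs[q, ])
    S[, q] <- protocol$s0 * exp(-protocol$bvals[q] * qf)
  }
  if (noise_sigma > 0) {
    S <- withr_seed(seed, {
      n1 <- matrix(stats::rnorm(nv * m, 0, noise_sigma), nv, m)
      n2 <- matrix(stats::rnorm(nv * m, 0, noise_sigma), nv, m)
      sqrt((S + n1)^2 + n2^2)
    })
  }
  volume(array(S, c(d, m)), spacing = tensors$spacing,
         affine = tensors$affine, units = "arbitrary")
}

#' Susceptibility-contrast acquisition parameters
#'
#' Parameters of the steady-state Delta-R2* experiment: a T2*-weighted
#' acquisition before and at USPIO steady state after contrast injection.
#' The physical constants enter only through the product
#' `gamma * delta_chi * B0`, which is exposed directly (the effective
#' susceptibility increase of an intravascular USPIO agent is
#' agent/dose-specific and rarely published).
#'
#' @param te echo time in seconds.
#' @param gamma proton gyromagnetic ratio (rad s^-1 T^-1).
#' @param delta_chi blood/tissue susceptibility difference at steady state
#'   (nonrationalised units).
#' @param b0 main field strength (T).
#' @param gamma_dchi_b0 optional override of the full product (s^-1); when
#'   given, the individual factors are ignored.
#' @return a `contrast_protocol`.
#' @export
contrast_protocol <- function(te = 0.013, gamma = 2.675e8, delta_chi = 1e-7,
                              b0 = 7, gamma_dchi_b0 = NULL) {
  if (te <= 0) stop("te must be > 0")
  if (is.null(gamma_dchi_b0)) {
    if (gamma <= 0 || delta_chi <= 0 || b0 <= 0)
      stop("gamma, delta_chi and b0 must be > 0")
    gamma_dchi_b0 <- gamma * delta_chi * b0
  }
  if (gamma_dchi_b0 <= 0) stop("gamma * delta_chi * B0 must be > 0")
  structure(list(te = te, gamma = gamma, delta_chi = delta_chi, b0 = b0,
                 gamma_dchi_b0 = gamma_dchi_b0),
            class = "contrast_protocol")
}

#' Simulate pre/post-contrast T2* signal pair from a CBV map
#'
#' Inverse of the steady-state CBV estimator:
#' `DeltaR2* = (CBV/100) * (4 pi / 3) * gamma * delta_chi * B0`, and
#' `S_post = S_pre * exp(-DeltaR2* * TE)`.
#'
#' @param cbv `morpho_volume` of CBV in % (>= 0).
#' @param protocol a [contrast_protocol()].
#' @param pre_signal `morpho_volume` of pre-contrast signal.
#' @param noise_sigma Rician noise SD applied to both volumes (0 = none).
#' @param seed RNG seed.
#' @return list of `pre` and `post` `morpho_volume`s.
#' @export
simulate_t2star <- function(cbv, protocol, pre_signal, noise_sigma = 0,
                            seed = 1L) {
  stopifnot(inherits(protocol, "contrast_protocol"))
  stop_if_geometry_differs(cbv, pre_signal)
  if (any(cbv$data < 0)) stop("cbv must be >= 0")
  dr2s <- (cbv$data / 100) * (4 * pi / 3) * protocol$gamma_dchi_b0
  post <- pre_signal$data * exp(-dr2s * protocol$te)
  pre <- pre_signal$data
  if (noise_sigma > 0) {
    d <- dim(pre)
    res <- withr_seed(seed, {
      rice <- function(s) {
        n1 <- array(stats::rnorm(length(s), 0, noise_sigma), d)
        n2 <- array(stats::rnorm(length(s), 0, noise_sigma), d)
        sqrt((s + n1)^2 + n2^2)
      }
      list(pre = rice(pre), post = rice(post))
    })
    pre <- res$pre; post <- res$post
  }
  list(pre = volume(pre, spacing = cbv$spacing, affine = cbv$affine,
                    units = "arbitrary"),
       post = volume(post, spacing = cbv$spacing, affine = cbv$affine,
                     units = "arbitrary"))
}

#' Piecewise-constant diffusion tensors from a tissue label map
#'
#' Assigns each phantom class a literature-scale tensor: isotropic grey
#' matter (~0.7e-3 mm^2/s), an anisotropic white-matter band with principal
#' axis along x (1.5, 0.3, 0.3) x 1e-3, near-free CSF. Per-class
#' multiplicative MD factors model pathology (e.g. the restricted diffusion
#' seen after irradiation).
#'
#' @param labels integer `morpho_volume` of phantom classes.
#' @param md_factors named numeric, multiplicative factor on the class
#'   tensor (names from [phantom_label_names()]).
#' @return a [tensor_map()].
#' @export
tensors_from_labels <- function(labels, md_factors = c()) {
  d <- grid_dim(labels)
  base <- list(
    cortex          = diag(c(0.8e-3, 0.8e-3, 0.8e-3)),
    striatum        = diag(c(0.7e-3, 0.7e-3, 0.7e-3)),
    corpus_callosum = diag(c(1.5e-3, 0.3e-3, 0.3e-3)),
    ventricles      = diag(c(2.5e-3, 2.5e-3, 2.5e-3))
  )
  t6 <- array(0, c(d, 6))
  lab <- labels$data
  nt <- phantom_label_names()
  for (i in seq_len(nrow(nt))) {
    nm <- nt$name[i]
    Dm <- base[[nm]]
    if (nm %in% names(md_factors)) Dm <- Dm * md_factors[[nm]]
    sel <- lab == nt$label_id[i]
    comp <- c(Dm[1, 1], Dm[2, 2], Dm[3, 3], Dm[1, 2], Dm[1, 3], Dm[2, 3])
    for (c in 1:6) {
      slab <- t6[, , , c]
      slab[sel] <- comp[c]
      t6[, , , c] <- slab
    }
  }
  tensor_map(t6, spacing = labels$spacing, affine = labels$affine)
}

#' Piecewise-constant CBV map from a tissue label map
#'
#' Default class values (cortex 6%, deep grey 4%, corpus callosum 3%,
#' ventricles 1%) follow the cortical > deep grey > white matter blood
#' volume ordering of rodent brain; per-class factors model vascular injury.
#'
#' @param labels integer `morpho_volume` of phantom classes.
#' @param cbv_factors named numeric multiplicative factors.
#' @param values named baseline CBV in % per class.
#' @return `morpho_volume` of CBV in %.
#' @export
cbv_from_labels <- function(labels, cbv_factors = c(),
                            values = c(cortex = 6, striatum = 4,
                                       corpus_callosum = 3,
                                       ventricles = 1)) {
  d <- grid_dim(labels)
  out <- array(0, d)
  nt <- phantom_label_names()
  for (i in seq_len(nrow(nt))) {
    nm <- nt$name[i]
    v <- values[[nm]]
    if (nm %in% names(cbv_factors)) v <- v * cbv_factors[[nm]]
    out[labels$data == nt$label_id[i]] <- v
  }
  volume(out, spacing = labels$spacing, affine = labels$affine, units = "%")
}
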