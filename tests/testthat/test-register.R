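# textured phantom pair used across the registration tests
reg_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- phantom_spec()
      ph <- make_phantom(sp)
      base <- add_texture(ph$volume, seed = 99)
      cache <<- list(sp = sp, ph = ph,
                     fixed = warp_and_degrade(
                       base, NULL,
                       phantom_spec(noise_sigma = 2, bias_amplitude = 0.1),
                       seed = 11),
                     base = base)
    }
    cache
  }
})

test_that("self-registration (affine) returns the identity transform", {
  fx <- reg_fixture()$fixed
  tf <- register_affine(fx, fx, kind = "rigid")
  pr <- affine_parameters(tf)
  expect_lt(max(abs(pr$angles_deg)), 0.1)
  expect_lt(max(abs(pr$translation_mm)), 0.05)
  expect_gte(attr(tf, "mi_final"), attr(tf, "mi_init"))
})

test_that("a known 5-degree / 1 mm rigid transform is recovered within 0.5 deg / 0.2 mm", {
  fix <- reg_fixture()$fixed
  sp <- reg_fixture()$sp
  th <- 5 * pi / 180
  ctr <- sp$grid_shape * sp$spacing / 2
  A <- diag(4)
  A[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A[1:3, 4] <- c(1, 0.5, 0) + ctr - A[1:3, 1:3] %*% ctr
  xyz <- voxel_world_coords(fix)
  q <- cbind(xyz, 1) %*% t(solve(A))
  mov <- volume(array(sample_volume(fix, q[, 1:3]), grid_dim(fix)),
                spacing = fix$spacing)
  tf <- register_affine(mov, fix, kind = "rigid")
  err <- tf$matrix %*% solve(A)
  rot_err <- acos(pmin(1, (sum(diag(err[1:3, 1:3])) - 1) / 2)) * 180 / pi
  expect_lt(rot_err, 0.5)
  brain_pts <- xyz[reg_fixture()$ph$labels$data > 0, ]
  brain_pts <- brain_pts[seq(1, nrow(brain_pts), length.out = 100), ]
  derr <- cbind(brain_pts, 1) %*% t(tf$matrix - A)
  expect_lt(mean(sqrt(rowSums(derr[, 1:3]^2))), 0.2)
  # MI trace is recorded per level and the final value brackets the initial
  expect_length(attr(tf, "mi_trace"), 3)
  expect_gte(attr(tf, "mi_final"), attr(tf, "mi_init"))
})

test_that("non-overlapping volumes are rejected", {
  fx <- reg_fixture()$fixed
  z <- volume(array(0, grid_dim(fx)), spacing = fx$spacing)
  expect_error(register_affine(z, fx, kind = "rigid"), "overlap")
})

test_that("rigid transforms validate their rotation block", {
  M <- diag(4); M[1, 1] <- 2
  expect_error(affine_transform(M, kind = "rigid"), "orthonormal")
  expect_error(affine_transform(matrix(0, 4, 4)), "invertible")
})

test_that("self-registration (nonlinear) yields a negligible field", {
  fx <- reg_fixture()$fixed
  reg <- register_nonlinear(fx, fx, iterations = c(10, 5, 5))
  mag <- sqrt(rowSums(matrix(reg$field$data, ncol = 3)^2))
  expect_lt(mean(mag), 0.05)
  J <- jacobian_determinant(reg$field)
  expect_gt(min(J$data), 0)
})

test_that("a focal contraction is recovered: landmark error halves and the blob-core log-Jacobian is correct", {
  fixt <- reg_fixture()
  sp <- fixt$sp
  base <- fixt$base
  ctr <- sp$grid_shape * sp$spacing / 2
  blob_c <- ctr + c(0, 0, 0.21 * sp$brain_axes[3])
  # landmark check on a strong focal contraction whose displacements are
  # well above the registration noise floor; sigma_update matched to the
  # deformation scale
  def <- make_deformation(list(focal_deformation(blob_c, 2.5, 0.7)), base)
  subj <- warp_volume(base, invert_displacement(def$field))
  reg <- register_nonlinear(subj, base, iterations = c(60, 30, 30),
                            sigma_total = 1, sigma_update = 2)
  # orientation preserved everywhere
  expect_gt(min(jacobian_determinant(reg$field)$data), 0)
  lm <- as.matrix(expand.grid(blob_c[1] + c(-2, 0, 2),
                              blob_c[2] + c(-2, 0, 2),
                              blob_c[3] + c(-2, 0, 2)))
  a <- 0.7^(1 / 3) - 1
  u_true <- t(apply(lm, 1, function(x) {
    dx <- x - blob_c
    a * dx * exp(-sum(dx^2) / (2 * 2.5^2))
  }))
  vox <- world_to_voxel(base, lm)
  u_rec <- sapply(1:3, function(c)
    morphorad:::.interp3_trilinear(as.double(reg$field$data[, , , c]),
                                   as.integer(grid_dim(base)),
                                   vox[, 1], vox[, 2], vox[, 3]))
  e_affine <- mean(sqrt(rowSums(u_true^2)))          # affine-only = identity
  e_nonlin <- mean(sqrt(rowSums((u_rec - u_true)^2)))
  expect_lt(e_nonlin, 0.5 * e_affine)

  # blob-core log-Jacobian of a 10% focal contraction after the full
  # register -> jacobian pipeline (regional mean: the estimand the DBM
  # statistics consume; the pointwise centre value of a regularised field
  # is noise-dominated at this effect size)
  def9 <- make_deformation(list(focal_deformation(blob_c, 2, 0.9)), base)
  subj9 <- warp_volume(base, invert_displacement(def9$field))
  reg9 <- register_nonlinear(subj9, base, iterations = c(60, 30, 30),
                             sigma_total = 1, sigma_update = 2)
  lj <- gaussian_smooth3(
    log_jacobian(jacobian_determinant(reg9$field))$data, 1)
  xyz <- voxel_world_coords(base)
  core <- array(sqrt(rowSums(sweep(xyz, 2, blob_c)^2)) < 1.5,
                grid_dim(base))
  expect_lt(abs(mean(lj[core]) - mean(log(def9$jacobian(xyz[core, ])))),
            0.02)
})

test_that("apply_transform: identity, exact shift on a ramp, and label-set preservation", {
  d <- c(16, 16, 8)
  ramp <- volume(array(rep(seq_len(d[1]) * 2, d[2] * d[3]), d),
                 spacing = c(1, 1, 1))
  idres <- structure(list(affine = affine_transform(diag(4), "rigid"),
                          field = NULL), class = "registration_result")
  out <- apply_transform(ramp, idres, target = ramp)
  expect_equal(out$data, ramp$data)
  # 1-voxel translation shifts values by the ramp slope
  A <- diag(4); A[1, 4] <- 1
  tres <- structure(list(affine = affine_transform(A), field = NULL),
                    class = "registration_result")
  sh <- apply_transform(ramp, tres, target = ramp)
  expect_equal(sh$data[2:15, , ], ramp$data[2:15, , ] + 2, tolerance = 1e-12)
  # labels through nearest-neighbour never invent values
  lab <- volume(array(sample(c(0, 3, 7), prod(d), TRUE), d),
                spacing = c(1, 1, 1))
  A2 <- diag(4); A2[1:3, 4] <- c(0.4, -0.3, 0.2)
  wres <- structure(list(affine = affine_transform(A2), field = NULL),
                    class = "registration_result")
  wl <- apply_transform(lab, wres, target = lab, interpolation = "nearest")
  expect_true(all(unique(as.vector(wl$data)) %in% c(0, 3, 7)))
})

test_that("template construction: single volume, identical volumes, and noise averaging", {
  fixt <- reg_fixture()
  sp <- fixt$sp
  expect_identical(build_template(list(fixt$fixed)), fixt$fixed)
  tpl <- build_template(list(fixt$fixed, fixt$fixed, fixt$fixed),
                        align = "none")
  expect_equal(tpl$data, fixt$fixed$data, tolerance = 1e-12)
  expect_error(build_template(list()), "at least one")
  # jittered phantoms: template correlates with the clean base at least as
  # well as each individual does
  base <- fixt$base
  vols <- lapply(1:6, function(i)
    warp_and_degrade(base, NULL, phantom_spec(noise_sigma = 4,
                                              bias_amplitude = 0),
                     seed = 50 + i))
  tpl6 <- build_template(vols, align = "none")
  ind <- vapply(vols, function(v) stats::cor(v$data[base$data > 0],
                                             base$data[base$data > 0]), 0)
  expect_gte(stats::cor(tpl6$data[base$data > 0], base$data[base$data > 0]),
             max(ind))
})
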