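test_that("phantom intensities equal class means exactly and counts match a brute-force voxel scan", {
  sp <- phantom_spec()
  ph <- make_phantom(sp)
  expect_true(all(ph$volume$data[ph$labels$data == 1] ==
                    sp$intensities[["cortex"]]))
  expect_true(all(ph$volume$data[ph$labels$data == 0] == 0))

  # independent oracle: re-evaluate the geometric predicates voxel by voxel
  d <- sp$grid_shape
  centre <- d * sp$spacing / 2
  ax <- sp$brain_axes
  counts <- c(`0` = 0, `1` = 0, `2` = 0, `3` = 0, `4` = 0)
  set.seed(7)
  # full scan is feasible at this size
  idx <- arrayInd(seq_len(prod(d)), d)
  xyz <- sweep(idx - 1, 2, sp$spacing, "*")
  dx <- sweep(xyz, 2, centre)
  rho <- sqrt((dx[, 1] / ax[1])^2 + (dx[, 2] / ax[2])^2 + (dx[, 3] / ax[3])^2)
  lab <- integer(nrow(xyz))
  lab[rho <= 1] <- 2L
  lab[rho <= 1 & rho >= 0.58] <- 1L
  lab[rho <= 1 & rho < 0.54 & dx[, 3] >= 0.04 * ax[3] &
        dx[, 3] <= 0.40 * ax[3]] <- 3L
  lab[rho <= 1 & rho >= 0.42 &
        (dx[, 1] / ax[1]) / pmax(rho, 1e-9) > 0.82] <- 1L
  for (s in c(-1, 1)) {
    sc <- if (s < 0) 1.2 else 0.85
    vc <- c(s * 0.30 * ax[1], 0.08 * s * ax[2], -0.05 * ax[3])
    vr <- sqrt(((dx[, 1] - vc[1]) / (sc * 0.14 * ax[1]))^2 +
               ((dx[, 2] - vc[2]) / (sc * 0.34 * ax[2]))^2 +
               ((dx[, 3] - vc[3]) / (sc * 0.16 * ax[3]))^2)
    lab[rho <= 1 & vr <= 1] <- 4L
  }
  expect_equal(as.vector(table(ph$labels$data)), as.vector(table(lab)))
})

test_that("degenerate or oversized geometry is rejected", {
  expect_error(phantom_spec(brain_axes = c(0, 5, 5)), "degenerate")
  expect_error(phantom_spec(grid_shape = c(8, 8, 8)), "too small")
})

test_that("focal blobs give the exact closed-form Jacobian at their centre", {
  sp <- small_spec()
  grid <- make_phantom(sp)$volume
  ctr <- sp$grid_shape * sp$spacing / 2
  for (ratio in c(0.9, 1.25)) {
    def <- make_deformation(list(focal_deformation(ctr, 1.5, ratio)), grid)
    expect_equal(def$jacobian(matrix(ctr, 1)), ratio, tolerance = 1e-12)
  }
  # empty list -> identity
  def0 <- make_deformation(list(), grid)
  expect_true(all(def0$field$data == 0))
  expect_true(all(abs(def0$jacobian(voxel_world_coords(grid)[1:5, ]) - 1) <
                    1e-15))
})

test_that("analytic Jacobian matches numerical differentiation of the map", {
  sp <- phantom_spec()
  grid <- make_phantom(sp)$volume
  ctr <- sp$grid_shape * sp$spacing / 2
  def <- make_deformation(list(focal_deformation(ctr, 2, 0.8)), grid)
  # numerical oracle: central differences of Phi at 10x refinement
  h <- min(sp$spacing) / 10
  set.seed(11)
  pts <- sweep(matrix(rnorm(3 * 40, sd = 1.2), ncol = 3), 2, ctr, "+")
  phi <- function(x) {
    a <- 0.8^(1 / 3) - 1
    dx <- x - ctr
    x + a * dx * exp(-sum(dx^2) / (2 * 2^2))
  }
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, ]
    G <- matrix(0, 3, 3)
    for (ax in 1:3) {
      e <- rep(0, 3); e[ax] <- h
      G[, ax] <- (phi(x + e) - phi(x - e)) / (2 * h)
    }
    expect_equal(def$jacobian(matrix(x, 1)), det(G), tolerance = 1e-3)
  }
})

test_that("blob validation: bad ratios, sigmas, centres, overlaps", {
  sp <- small_spec()
  grid <- make_phantom(sp)$volume
  expect_error(focal_deformation(c(4, 4, 6), 1, 0), "volume_ratio")
  expect_error(focal_deformation(c(4, 4, 6), -1, 1.1), "sigma")
  expect_error(make_deformation(
    list(focal_deformation(c(99, 4, 6), 1, 1.1)), grid), "outside")
  expect_warning(make_deformation(
    list(focal_deformation(c(4, 4, 6), 1, 0.9),
         focal_deformation(c(4.5, 4, 6), 1, 1.1)), grid), "overlap")
})

test_that("warp_and_degrade is identity without field, noise or bias", {
  sp <- small_spec(noise_sigma = 0, bias_amplitude = 0)
  ph <- make_phantom(sp)
  out <- warp_and_degrade(ph$volume, NULL, sp)
  expect_equal(out$data, ph$volume$data)
})

test_that("bias field multiplies intensities exactly where input is positive", {
  sp <- small_spec(noise_sigma = 0, bias_amplitude = 0.3)
  ph <- make_phantom(sp)
  out <- warp_and_degrade(ph$volume, NULL, sp, seed = 9)
  b <- make_bias_field(ph$volume, 0.3, seed = 9)
  pos <- ph$volume$data > 0
  expect_equal(out$data[pos] / ph$volume$data[pos], b$data[pos],
               tolerance = 1e-12)
})

test_that("zero-signal background follows the Rayleigh noise floor", {
  sp <- small_spec(noise_sigma = 4, bias_amplitude = 0)
  ph <- make_phantom(sp)
  out <- warp_and_degrade(ph$volume, NULL, sp, seed = 2)
  bg <- out$data[ph$labels$data == 0]
  expect_gt(length(bg), 1e4)
  expect_equal(mean(bg), 4 * sqrt(pi / 2), tolerance = 0.02)
  expect_equal(stats::var(bg), (2 - pi / 2) * 16, tolerance = 0.05)
})

test_that("displacement inversion composes to identity", {
  sp <- small_spec()
  grid <- make_phantom(sp)$volume
  ctr <- sp$grid_shape * sp$spacing / 2
  def <- make_deformation(list(focal_deformation(ctr, 1.5, 0.8)), grid)
  inv <- invert_displacement(def$field)
  # sample u at x + v(x), add v: should vanish
  xyz <- voxel_world_coords(grid)
  v <- matrix(inv$data, ncol = 3)
  comp <- v
  for (c in 1:3) {
    vox <- world_to_voxel(grid, xyz + v)
    comp[, c] <- v[, c] +
      morphorad:::.interp3_trilinear(as.double(def$field$data[, , , c]),
                                     as.integer(grid_dim(grid)),
                                     vox[, 1], vox[, 2], vox[, 3])
  }
  expect_lt(max(abs(comp)), 1e-4)
})
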