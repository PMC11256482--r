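test_that("noise-free tensor fit is exact to machine precision", {
  sp <- small_spec()
  labels <- make_phantom(sp)$labels
  tens <- tensors_from_labels(labels)
  pr <- dwi_protocol()
  dwi <- simulate_dwi(tens, pr)
  mask <- volume(array(as.double(labels$data > 0), grid_dim(labels)),
                 spacing = sp$spacing)
  fit <- fit_dti(dwi, pr, mask)
  sel <- rep(labels$data > 0, 6)
  expect_lt(max(abs(fit$tensor[sel] - tens$tensor[sel])), 1e-10)
  # eigenvalues of the anisotropic class and principal-axis direction
  cc <- which(labels$data == 3)[1]
  ijk <- arrayInd(cc, grid_dim(labels))
  ev <- fit$evals[ijk[1], ijk[2], ijk[3], ]
  expect_equal(ev, c(1.5e-3, 0.3e-3, 0.3e-3), tolerance = 1e-10,
               ignore_attr = TRUE)
  v1 <- fit$evec1[ijk[1], ijk[2], ijk[3], ]
  angle <- acos(pmin(1, abs(sum(v1 * c(1, 0, 0))))) * 180 / pi
  expect_lt(angle, 0.1)
  # s0 recovered
  expect_equal(fit$s0$data[labels$data > 0][1], pr$s0, tolerance = 1e-10)
})

test_that("MD bias stays below 5% at Rician SNR 30", {
  d <- c(11, 11, 11)   # 1331 voxels
  t6 <- array(0, c(d, 6)); t6[, , , 1:3] <- 0.7e-3
  tm <- tensor_map(t6)
  pr <- dwi_protocol(s0 = 1000)
  dwi <- simulate_dwi(tm, pr, noise_sigma = 1000 / 30, seed = 8)
  fit <- fit_dti(dwi, pr)
  sc <- dti_scalars(fit)
  md_med <- stats::median(sc$MD$data)
  expect_lt(abs(md_med - 700) / 700, 0.05)
})

test_that("diffusion scalars: definitions, units and ordering", {
  d <- c(2, 2, 2)
  t6 <- array(0, c(d, 6))
  t6[, , , 1] <- 1.5e-3; t6[, , , 2] <- 0.3e-3; t6[, , , 3] <- 0.3e-3
  sc <- dti_scalars(tensor_map(t6))
  expect_equal(sc$MD$data[1, 1, 1], 700, tolerance = 1e-9)
  expect_equal(sc$AD$data[1, 1, 1], 1500, tolerance = 1e-9)
  expect_equal(sc$RD$data[1, 1, 1], 300, tolerance = 1e-9)
  # isotropic: all equal
  iso <- array(0, c(d, 6)); iso[, , , 1:3] <- 0.9e-3
  sci <- dti_scalars(tensor_map(iso))
  expect_equal(sci$MD$data, sci$AD$data, tolerance = 1e-12)
  expect_equal(sci$MD$data, sci$RD$data, tolerance = 1e-12)
  # MD equals trace/3 computed without eigendecomposition
  set.seed(2)
  r6 <- array(rnorm(prod(d) * 6, sd = 1e-4), c(d, 6))
  r6[, , , 1:3] <- abs(r6[, , , 1:3]) + 1e-3
  scr <- dti_scalars(tensor_map(r6))
  tr3 <- (r6[, , , 1] + r6[, , , 2] + r6[, , , 3]) / 3 * 1e6
  expect_equal(scr$MD$data, tr3, tolerance = 1e-12)
  # AD >= MD >= RD always
  expect_true(all(scr$AD$data >= scr$MD$data - 1e-12))
  expect_true(all(scr$MD$data >= scr$RD$data - 1e-12))
})

test_that("delta-R2* closed forms and flags", {
  d <- c(4, 4, 4)
  pre <- volume(array(exp(1) * 100, d), spacing = c(1, 1, 1))
  post <- volume(array(100, d), spacing = c(1, 1, 1))
  dr <- delta_r2star(pre, post, te = 0.013)
  expect_equal(dr$data[1, 1, 1], 1 / 0.013, tolerance = 1e-12)
  # equal signals -> zero
  dr0 <- delta_r2star(post, post, te = 0.013)
  expect_true(all(dr0$data == 0))
  expect_equal(attr(dr0, "n_nonpositive_dr2s"), length(dr0$data))
  # non-positive input masked out
  bad <- volume(array(c(0, rep(50, 63)), d), spacing = c(1, 1, 1))
  drb <- delta_r2star(bad, post, te = 0.013)
  expect_equal(attr(drb, "n_nonpositive_signal"), 1L)
  expect_true(is.na(drb$data[1, 1, 1]))
  expect_error(delta_r2star(pre, post, te = 0), "te")
})

test_that("CBV estimator is the scaled inverse of the simulator (round trip)", {
  sp <- small_spec()
  labels <- make_phantom(sp)$labels
  cbv <- cbv_from_labels(labels)
  cp <- contrast_protocol()
  pre <- volume(array(800, grid_dim(labels)), spacing = sp$spacing)
  pair <- simulate_t2star(cbv, cp, pre)
  rec <- cbv_map(delta_r2star(pair$pre, pair$post, cp$te), cp)
  expect_lt(max(abs(rec$data - cbv$data)), 1e-9)
  # linearity
  rec2 <- cbv_map(volume(2 * delta_r2star(pair$pre, pair$post, cp$te)$data,
                         spacing = sp$spacing), cp)
  expect_equal(rec2$data, 2 * rec$data, tolerance = 1e-12)
  # zero in, zero out
  expect_equal(cbv_map(volume(array(0, c(2, 2, 2)), spacing = c(1, 1, 1)),
                       cp)$data, array(0, c(2, 2, 2)))
})

test_that("noisy CBV keeps masked-median error under 5% at SNR 50", {
  sp <- small_spec()
  labels <- make_phantom(sp)$labels
  cbv <- cbv_from_labels(labels)
  cp <- contrast_protocol()
  pre <- volume(array(800, grid_dim(labels)), spacing = sp$spacing)
  pair <- simulate_t2star(cbv, cp, pre, noise_sigma = 800 / 50, seed = 4)
  rec <- cbv_map(delta_r2star(pair$pre, pair$post, cp$te), cp)
  ctx <- labels$data == 1
  err <- abs(stats::median(rec$data[ctx]) - 6) / 6
  expect_lt(err, 0.05)
})
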