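mk_maps <- function(X, d, mask) {
  lapply(seq_len(ncol(X)), function(i) {
    a <- array(0, d); a[mask$data > 0] <- X[, i]
    volume(a, spacing = mask$spacing)
  })
}

test_that("voxel-wise t equals the scalar pooled t-test and is antisymmetric", {
  d <- c(3, 1, 1)
  mask <- volume(array(1, d), spacing = c(1, 1, 1))
  A <- cbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  B <- cbind(c(2, 2, 2), c(3, 3, 3), c(4, 4, 4))
  tm <- voxelwise_ttest(mk_maps(A, d, mask), mk_maps(B, d, mask), mask)
  oracle <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)$statistic
  expect_equal(unname(tm$data[1, 1, 1]), unname(oracle), tolerance = 1e-12)
  expect_equal(attr(tm, "df"), 4L)
  # swap groups -> negated
  tm2 <- voxelwise_ttest(mk_maps(B, d, mask), mk_maps(A, d, mask), mask)
  expect_equal(tm2$data, -tm$data)
  # identical groups -> zero t everywhere
  tm3 <- voxelwise_ttest(mk_maps(A, d, mask), mk_maps(A, d, mask), mask)
  expect_true(all(tm3$data == 0))
  # all subjects identical -> zero variance, flagged not NaN
  C <- cbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  tm4 <- voxelwise_ttest(mk_maps(C, d, mask), mk_maps(C, d, mask), mask)
  expect_true(all(tm4$data == 0))
  expect_equal(attr(tm4, "n_zero_variance"), 3L)
})

test_that("tiny groups trigger the achievable-alpha warning with the exact floor", {
  d <- c(4, 1, 1)
  mask <- volume(array(1, d), spacing = c(1, 1, 1))
  set.seed(1)
  A <- matrix(rnorm(8), 4, 2); B <- matrix(rnorm(8), 4, 2)
  expect_warning(
    sig <- fwe_correct(mk_maps(A, d, mask), mk_maps(B, d, mask), mask,
                       alpha = 0.01, n_perm = 100, seed = 1),
    "floor")
  expect_equal(attr(sig, "alpha_floor"), 1 / choose(4, 2))
  expect_equal(attr(sig, "n_permutations"), 6L)
  expect_true(attr(sig, "exhaustive"))
})

test_that("maxT correction controls family-wise error on null data", {
  # 50 seeded null simulations, 6 vs 6 smooth random maps, alpha 0.05 with
  # 200 permutations: empirical FWER must lie inside the binomial band
  d <- c(12, 12, 8)
  mask <- volume(array(1, d), spacing = c(1, 1, 1))
  n_any <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    maps <- lapply(1:12, function(i)
      volume(gaussian_smooth3(array(rnorm(prod(d)), d), 1),
             spacing = c(1, 1, 1)))
    sig <- fwe_correct(maps[1:6], maps[7:12], mask, alpha = 0.05,
                       n_perm = 200, seed = s)
    if (any(sig$data != 0)) n_any <- n_any + 1
  }
  ci <- stats::binom.test(n_any, 50)$conf.int
  expect_lte(ci[1], 0.05)   # CI must not exclude the nominal level from above
  expect_lte(n_any, 7)      # and the rate must not be grossly anticonservative
})

test_that("maxT detects a strong seeded effect overlapping the seed region", {
  d <- c(16, 16, 8)
  mask <- volume(array(1, d), spacing = c(1, 1, 1))
  seedblk <- array(FALSE, d); seedblk[6:10, 6:10, 3:6] <- TRUE
  hits <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    maps <- lapply(1:12, function(i) {
      a <- gaussian_smooth3(array(rnorm(prod(d)), d), 1)
      sdn <- stats::sd(a)
      if (i <= 6) a[seedblk] <- a[seedblk] + 3 * sdn
      volume(a, spacing = c(1, 1, 1))
    })
    sig <- fwe_correct(maps[1:6], maps[7:12], mask, alpha = 0.05,
                       n_perm = 300, seed = s)
    pos <- sig$data > 0
    dice <- 2 * sum(pos & seedblk) / (sum(pos) + sum(seedblk))
    if (!is.nan(dice) && dice >= 0.3) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of simulations
})

test_that("maxT decisions are invariant under common monotone rescaling", {
  d <- c(8, 8, 4)
  mask <- volume(array(1, d), spacing = c(1, 1, 1))
  set.seed(9)
  maps <- lapply(1:8, function(i)
    volume(array(rnorm(prod(d), mean = 10), d), spacing = c(1, 1, 1)))
  s1 <- suppressWarnings(   # small-group alpha-floor warning is expected
    fwe_correct(maps[1:4], maps[5:8], mask, alpha = 0.1, n_perm = 70,
                seed = 2))
  scaled <- lapply(maps, function(v) volume(3 * v$data + 7,
                                            spacing = v$spacing))
  s2 <- suppressWarnings(
    fwe_correct(scaled[1:4], scaled[5:8], mask, alpha = 0.1, n_perm = 70,
                seed = 2))
  expect_identical(s1$data, s2$data)
})

test_that("cluster labelling matches a flood-fill oracle for 6 and 26 connectivity", {
  set.seed(31)
  d <- c(16, 16, 16)
  m <- array(rbinom(prod(d), 1, 0.25), d)
  sig <- volume(m, spacing = c(1, 1, 1))
  flood_count <- function(m, conn) {
    d <- dim(m); lab <- array(0L, d); nxt <- 0L
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(offs != 0) > 0, ]
    if (conn == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
    for (v in which(m == 1)) {
      if (lab[v] != 0) next
      nxt <- nxt + 1L
      stack <- v
      while (length(stack)) {
        cur <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (lab[cur] != 0) next
        lab[cur] <- nxt
        ijk <- arrayInd(cur, d)
        nb <- sweep(offs, 2, as.integer(ijk), "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
          nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
        nb <- nb[ok, , drop = FALSE]
        lin <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
        stack <- c(stack, lin[m[lin] == 1 & lab[lin] == 0])
      }
    }
    nxt
  }
  for (conn in c(6, 26)) {
    cs <- label_clusters(sig, connectivity = conn)
    expect_equal(nrow(cs$clusters), flood_count(m, conn),
                 label = paste("connectivity", conn))
  }
})

test_that("clusters are signed, disjoint, complete and size-ordered", {
  d <- c(12, 12, 6)
  a <- array(0, d)
  a[2:4, 2:4, 2:4] <- 1    # 27 voxels positive
  a[8:10, 8:10, 2:4] <- 1  # 27 voxels positive
  a[6, 6, 1] <- -1
  sig <- volume(a, spacing = c(0.5, 0.5, 1))
  cs <- label_clusters(sig)
  expect_equal(nrow(cs$clusters), 3)
  expect_equal(sum(cs$clusters$sign > 0), 2)
  expect_equal(cs$clusters$n_voxels[1:2], c(27, 27))
  expect_equal(cs$clusters$volume_mm3[1], 27 * 0.25)
  # ties broken by centroid: the (2:4) block comes before (8:10)
  expect_lt(cs$clusters$cx[1], cs$clusters$cx[2])
  # partition completeness
  expect_equal(sort(unlist(cs$members)), sort(which(a != 0)))
  # empty mask
  cs0 <- label_clusters(volume(array(0, d), spacing = c(1, 1, 1)))
  expect_equal(nrow(cs0$clusters), 0)
})

test_that("cluster proportions are exact percentages of the brain mask", {
  d <- c(10, 10, 10)
  a <- array(0, d); a[1:38] <- -1
  sig <- volume(a, spacing = c(1, 1, 1))
  brain <- volume(array(1, d), spacing = c(1, 1, 1))
  cs <- label_clusters(sig, connectivity = 26)
  pr <- cluster_proportions(cs, brain)
  expect_equal(unname(pr["negative_pct"]), 3.8)
  expect_equal(unname(pr["positive_pct"]), 0)
  # independent voxel count
  expect_equal(unname(pr["negative_pct"]),
               100 * sum(sig$data < 0) / sum(brain$data > 0))
  expect_error(cluster_proportions(cs, volume(array(0, d),
                                              spacing = c(1, 1, 1))),
               "empty")
})
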