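test_that("ROI means match brute-force sums and handle NAs explicitly", {
  d <- c(4, 4, 4)
  m <- volume(array(seq_len(64), d), spacing = c(1, 1, 1))
  roi <- volume(array(0, d), spacing = c(1, 1, 1))
  roi$data[1:4] <- 1
  expect_equal(as.numeric(extract_roi_means(m, roi)), 2.5)
  # constant map
  cmap <- volume(array(7, d), spacing = c(1, 1, 1))
  expect_equal(as.numeric(extract_roi_means(cmap, roi)), 7)
  # random ROI vs brute force
  set.seed(3)
  sel <- sample(64, 20)
  expect_equal(as.numeric(extract_roi_means(m, sel)),
               sum(m$data[sel]) / 20)
  # NA handling
  m$data[1] <- NA
  got <- extract_roi_means(m, roi)
  expect_equal(as.numeric(got), mean(c(2, 3, 4)))
  expect_equal(attr(got, "n_na"), 1L)
  expect_error(extract_roi_means(m, volume(array(0, d),
                                           spacing = c(1, 1, 1))), "empty")
})

balanced_toy <- function() {
  # 2 groups x 3 times x 3 replicates, known values
  expand.grid(rep = 1:3, group = c("a", "b"),
              timepoint = c("t1", "t2", "t3")) |>
    transform(y = c(10, 11, 12,  20, 21, 22,
                    13, 14, 15,  24, 25, 23,
                    16, 18, 17,  30, 29, 31))
}

test_that("two-way ANOVA F matches a hand-computed sums-of-squares oracle on balanced data", {
  df <- balanced_toy()
  res <- two_way_anova_lsd(df, "y")
  # brute-force sums of squares for the balanced case
  y <- df$y; n <- length(y)
  gm <- mean(y)
  ssa <- sum(tapply(y, df$group, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, df$timepoint, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, list(df$group, df$timepoint), mean)
  ssc <- 3 * sum((cellm - gm)^2)
  ssab <- ssc - ssa - ssb
  sse <- sum((y - ave(y, df$group, df$timepoint))^2)
  mse <- sse / (n - 6)
  expect_equal(res$anova$sum_sq, c(ssa, ssb, ssab), tolerance = 1e-10)
  expect_equal(res$anova$F, c(ssa / 1, ssb / 2, ssab / 2) / mse,
               tolerance = 1e-10)
  expect_equal(res$mse, mse, tolerance = 1e-12)
})

test_that("Type II sums of squares agree with the car oracle on unbalanced data", {
  skip_if_not_installed("car")
  df <- balanced_toy()
  df <- df[-c(1, 8), ]   # unbalance two cells
  res <- two_way_anova_lsd(df, "y")
  fit <- stats::lm(y ~ group * timepoint, data = df,
                   contrasts = list(group = "contr.sum",
                                    timepoint = "contr.sum"))
  ca <- car::Anova(fit, type = 2)
  expect_equal(res$anova$sum_sq, ca$`Sum Sq`[1:3], tolerance = 1e-10)
  expect_equal(res$anova$F, ca$`F value`[1:3], tolerance = 1e-10)
})

test_that("LSD contrasts use the pooled MSE and per-cell means", {
  df <- balanced_toy()
  res <- two_way_anova_lsd(df, "y")
  row <- res$lsd[res$lsd$timepoint == "t1", ]
  est <- mean(df$y[df$group == "a" & df$timepoint == "t1"]) -
    mean(df$y[df$group == "b" & df$timepoint == "t1"])
  expect_equal(row$estimate, est)
  se <- sqrt(res$mse * (1 / 3 + 1 / 3))
  expect_equal(row$t, est / se, tolerance = 1e-12)
  expect_equal(row$p, 2 * pt(abs(est / se), res$df_resid, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("degenerate ANOVA inputs are flagged or rejected", {
  df <- balanced_toy(); df$y <- 5
  expect_warning(res <- two_way_anova_lsd(df, "y"), "zero residual")
  expect_true(all(is.na(res$anova$F)))
  df2 <- balanced_toy()
  df2 <- df2[!(df2$group == "a" & df2$timepoint == "t1"), ]
  expect_error(two_way_anova_lsd(df2, "y"), "empty cells")
})

test_that("time main effect is invariant to relabeling groups within cells", {
  df <- balanced_toy()
  res1 <- two_way_anova_lsd(df, "y")
  df2 <- df
  # swap group labels within each timepoint (a<->b wholesale)
  df2$group <- ifelse(df2$group == "a", "b", "a")
  res2 <- two_way_anova_lsd(df2, "y")
  expect_equal(res1$anova$sum_sq[2], res2$anova$sum_sq[2], tolerance = 1e-10)
})

test_that("Pearson matrix: perfect, orthogonal and textbook Fisher-z cases", {
  x <- 1:10
  df <- data.frame(a = x, b = 2 * x)
  cm <- pearson_matrix(df)
  expect_equal(unname(cm$r["a", "b"]), 1)
  expect_equal(unname(cm$p["a", "b"]), 0)
  expect_true(all(diag(cm$r) == 1))
  expect_true(isSymmetric(cm$r))

  # orthogonal mean-centred pair
  a <- c(-1, 1, -1, 1); b <- c(-1, -1, 1, 1)
  cm0 <- pearson_matrix(data.frame(a = a, b = b))
  expect_equal(unname(cm0$r["a", "b"]), 0)
  expect_equal(unname(cm0$p["a", "b"]), 1)

  # r = 0.6, n = 10 against an independent normal-CDF evaluation
  set.seed(10)
  repeat {
    x <- rnorm(10); e <- rnorm(10)
    y <- 0.6 * scale(x) + e * 0.01
    y <- as.vector(scale(y))
    # construct exact r = 0.6 by Gram-Schmidt
    xs <- as.vector(scale(x))
    z <- as.vector(scale(resid(lm(e ~ xs))))
    y <- 0.6 * xs + sqrt(1 - 0.36) * z
    break
  }
  cm6 <- pearson_matrix(data.frame(x = xs, y = y))
  r <- unname(cm6$r["x", "y"])
  expect_equal(r, 0.6, tolerance = 1e-10)
  p_oracle <- 2 * (1 - pnorm(atanh(0.6) * sqrt(7)))
  expect_equal(unname(cm6$p["x", "y"]), p_oracle, tolerance = 1e-12)
})

test_that("correlations are invariant under affine rescaling of columns", {
  set.seed(4)
  df <- as.data.frame(matrix(rnorm(60), 15, 4))
  cm1 <- pearson_matrix(df)
  df2 <- df
  df2[[2]] <- 5 * df2[[2]] - 3
  df2[[4]] <- -0.1 * df2[[4]] + 100
  cm2 <- pearson_matrix(df2)
  expect_equal(abs(cm1$r), abs(cm2$r), tolerance = 1e-12)
  expect_equal(cm1$p, cm2$p, tolerance = 1e-12)
})

test_that("small-n pairs report r with NA p and a warning", {
  df <- data.frame(a = c(1, 2, 3, NA, NA), b = c(2, 1, 3, NA, NA))
  expect_warning(cm <- pearson_matrix(df), "n < 4")
  expect_true(is.na(cm$p["a", "b"]))
  expect_false(is.na(cm$r["a", "b"]))
})

test_that("planted JD~MD coupling at the anchor time is recovered in the wide table", {
  # synthetic study table: irradiated subjects at 1M have linearly coupled
  # JD and MD; the anchored matrix must flag JD_1M ~ MD_1M with the
  # planted (negative) sign in most simulations
  hits <- 0
  for (s in 1:25) {
    set.seed(300 + s)
    subj <- sprintf("S%02d", 1:12)
    rows <- NULL
    for (tp in c("1M", "6M")) {
      jd <- rnorm(12, 0, 0.02)
      md <- 700 + rnorm(12, 0, 20)
      if (tp == "1M") {
        jd[7:12] <- jd[7:12] - 0.06
        md[7:12] <- 700 + 2000 * jd[7:12] + rnorm(6, 0, 8)
      }
      rows <- rbind(rows, data.frame(
        subject_id = subj, group = rep(c("control", "irradiated"), each = 6),
        timepoint = tp, JD = jd, MD = md))
    }
    wide <- study_wide_table(rows, params = c("JD", "MD"))
    cm <- pearson_matrix(wide[, -(1:2)])
    r <- cm$r["JD_1M", "MD_1M"]
    if (!is.na(r) && r > 0 && cm$significant["JD_1M", "MD_1M"]) hits <- hits + 1
  }
  expect_gte(hits, 20)  # >= 80% of 25 simulations
})
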