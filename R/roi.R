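#' Mean of a parametric map inside an ROI
#'
#' @param map `morpho_volume`.
#' @param roi binary `morpho_volume` (same space) or an integer voxel index
#'   vector.
#' @return arithmetic mean over ROI voxels, NAs excluded;
#'   `attr(, "n_na")` reports how many were excluded.
#' @export
extract_roi_means <- function(map, roi) {
  stopifnot(is_volume(map))
  vals <- if (is_volume(roi)) {
    stop_if_geometry_differs(map, roi)
    map$data[roi$data > 0]
  } else map$data[roi]
  if (length(vals) == 0) stop("empty ROI")
  out <- mean(vals, na.rm = TRUE)
  attr(out, "n_na") <- sum(is.na(vals))
  out
}

#' Two-way ANOVA (group x time) with Fisher LSD post-hoc tests
#'
#' Fixed-effects two-factor ANOVA with interaction, Type II sums of squares
#' (each main effect adjusted for the other; appropriate for the unbalanced
#' cells of attrition-prone longitudinal animal studies), computed by model
#' comparison of least-squares fits. Fisher's LSD then compares the two
#' groups at each timepoint with t-tests that use the pooled residual mean
#' square of the full model (no multiplicity adjustment -- that is what
#' LSD is).
#'
#' @param table data.frame with at least the response and the two factor
#'   columns.
#' @param response name of the response column.
#' @param factors length-2 character: grouping factor, time factor.
#' @return list: `anova` (data.frame with df, SS, MS, F, p), `lsd`
#'   (pairwise group contrasts per timepoint), `mse`, `df_resid`.
#' @export
two_way_anova_lsd <- function(table, response,
                              factors = c("group", "timepoint")) {
  stopifnot(all(c(response, factors) %in% names(table)))
  df <- table[stats::complete.cases(table[, c(response, factors)]), ]
  df[[factors[1]]] <- factor(df[[factors[1]]])
  df[[factors[2]]] <- factor(df[[factors[2]]])
  if (nlevels(df[[factors[1]]]) < 2 || nlevels(df[[factors[2]]]) < 2)
    stop("need >= 2 levels per factor")
  cells <- table(df[[factors[1]]], df[[factors[2]]])
  if (any(cells == 0))
    stop("empty cells: ",
         paste(apply(which(cells == 0, arr.ind = TRUE), 1, function(ij)
           paste(rownames(cells)[ij[1]], colnames(cells)[ij[2]], sep = ":")),
           collapse = ", "))
  if (any(cells < 2)) stop("need >= 2 observations per cell")
  y <- df[[response]]
  fA <- stats::as.formula(paste(response, "~", factors[1]))
  fB <- stats::as.formula(paste(response, "~", factors[2]))
  fAB <- stats::as.formula(paste(response, "~", factors[1], "+", factors[2]))
  fFull <- stats::as.formula(paste(response, "~", factors[1], "*", factors[2]))
  rss <- function(f) sum(stats::resid(stats::lm(f, data = df))^2)
  rss_A <- rss(fA); rss_B <- rss(fB); rss_AB <- rss(fAB)
  full <- stats::lm(fFull, data = df)
  rss_full <- sum(stats::resid(full)^2)
  a <- nlevels(df[[factors[1]]]); b <- nlevels(df[[factors[2]]])
  df_A <- a - 1L; df_B <- b - 1L; df_AB <- (a - 1L) * (b - 1L)
  df_res <- nrow(df) - a * b
  mse <- rss_full / df_res
  ss <- c(rss_B - rss_AB,   # factor A adjusted for B (Type II)
          rss_A - rss_AB,   # factor B adjusted for A
          rss_AB - rss_full)
  dfs <- c(df_A, df_B, df_AB)
  ms <- ss / dfs
  if (mse <= .Machine$double.eps * max(1, mean(y)^2)) {
    Fv <- rep(NA_real_, 3)
    pv <- rep(NA_real_, 3)
    warning("zero residual variance: F statistics undefined")
  } else {
    Fv <- ms / mse
    pv <- stats::pf(Fv, dfs, df_res, lower.tail = FALSE)
  }
  an <- data.frame(term = c(factors[1], factors[2],
                            paste(factors, collapse = ":")),
                   df = dfs, sum_sq = ss, mean_sq = ms, F = Fv, p = pv,
                   stringsAsFactors = FALSE)
  # Fisher LSD: group contrasts within each timepoint, pooled MSE
  glev <- levels(df[[factors[1]]]); tlev <- levels(df[[factors[2]]])
  lsd <- NULL
  for (tp in tlev) {
    for (i in seq_len(length(glev) - 1)) for (j in seq(i + 1, length(glev))) {
      yi <- y[df[[factors[1]]] == glev[i] & df[[factors[2]]] == tp]
      yj <- y[df[[factors[1]]] == glev[j] & df[[factors[2]]] == tp]
      se <- sqrt(mse * (1 / length(yi) + 1 / length(yj)))
      tstat <- if (se > 0) (mean(yi) - mean(yj)) / se else NA_real_
      lsd <- rbind(lsd, data.frame(
        timepoint = tp, contrast = paste(glev[i], "-", glev[j]),
        estimate = mean(yi) - mean(yj), t = tstat,
        p = if (is.na(tstat)) NA_real_ else
          2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE),
        stringsAsFactors = FALSE))
    }
  }
  list(anova = an, lsd = lsd, mse = mse, df_resid = df_res)
}

#' Pearson correlation matrix with Fisher-z p-values
#'
#' Pairwise-complete Pearson correlations between numeric columns; the
#' p-value of each pair comes from the Fisher z statistic
#' `z = atanh(r) * sqrt(n - 3)` against the standard normal (two-sided),
#' the classical "Z test" for a correlation coefficient. Pairs with fewer
#' than 4 complete observations get `p = NA` with a warning (the z test is
#' undefined there); `|r| = 1` maps to `p = 0`.
#'
#' @param data data.frame of numeric columns (observations x parameters).
#' @param vars columns to use (default: all numeric).
#' @param p_method `"fisher-z"` (default) or `"t"` (the t-distribution
#'   alternative, for sensitivity checks).
#' @return a `correlation_matrix`: matrices `r`, `p`, `n` and logical
#'   `significant` (p < 0.05).
#' @export
pearson_matrix <- function(data, vars = NULL, p_method = c("fisher-z", "t")) {
  p_method <- match.arg(p_method)
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, TRUE)]
  X <- as.matrix(data[, vars, drop = FALSE])
  k <- ncol(X)
  r <- diag(1, k); p <- matrix(NA_real_, k, k); n <- matrix(0L, k, k)
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(vars, vars)
  diag(p) <- 0; diag(n) <- colSums(is.finite(X))
  small <- FALSE
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    ok <- is.finite(X[, i]) & is.finite(X[, j])
    nn <- sum(ok)
    n[i, j] <- n[j, i] <- nn
    if (nn < 2 || stats::sd(X[ok, i]) == 0 || stats::sd(X[ok, j]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    rr <- stats::cor(X[ok, i], X[ok, j])
    r[i, j] <- r[j, i] <- rr
    if (nn < 4) { small <- TRUE; next }
    if (abs(rr) >= 1) {
      pp <- 0
    } else if (p_method == "fisher-z") {
      z <- atanh(rr) * sqrt(nn - 3)
      pp <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    } else {
      tt <- rr * sqrt((nn - 2) / (1 - rr^2))
      pp <- 2 * stats::pt(abs(tt), nn - 2, lower.tail = FALSE)
    }
    p[i, j] <- p[j, i] <- pp
  }
  if (small)
    warning("some pairs have n < 4: correlation reported, p set to NA")
  structure(list(r = r, p = p, n = n, significant = !is.na(p) & p < 0.05,
                 p_method = p_method),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> r:\n")
  print(round(x$r, 3))
  cat("significant (p < 0.05):\n")
  print(x$significant)
  invisible(x)
}

#' Wide per-subject parameter table for anchored correlation analysis
#'
#' Reshapes a long study table (one row per subject x timepoint) into one
#' row per subject with columns `<param>_<timepoint>`, e.g. `JD_1M`,
#' `MD_6M`. Used for the time-anchored correlation matrices where the
#' log-Jacobian at a reference timepoint is correlated with the other
#' parameters across timepoints.
#'
#' @param table long data.frame with `subject_id`, `timepoint` and
#'   parameter columns.
#' @param params parameter column names to spread.
#' @return wide data.frame, one row per subject (plus `group`).
#' @export
study_wide_table <- function(table, params = c("JD", "CBV", "MD", "AD", "RD")) {
  subs <- unique(table$subject_id)
  tps <- unique(table$timepoint)
  out <- data.frame(subject_id = subs, stringsAsFactors = FALSE)
  out$group <- table$group[match(subs, table$subject_id)]
  for (p in intersect(params, names(table)))
    for (tp in tps) {
      col <- paste0(p, "_", tp)
      sel <- table$timepoint == tp
      out[[col]] <- table[[p]][sel][match(subs, table$subject_id[sel])]
    }
  out
}
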