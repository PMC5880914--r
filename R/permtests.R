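# ---- shared helpers ---------------------------------------------------------

new_permutation_test <- function(method, statistic, p_value, n_permutations,
                                 seed, extra = list()) {
  structure(
    c(list(
      method = method, statistic = statistic, p_value = p_value,
      n_permutations = n_permutations, seed = seed
    ), extra),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(
    "<permutation_test> %s: %s = %.4f, p = %s (%s permutations)\n",
    x$method, names(x$statistic)[1], x$statistic[1],
    format(x$p_value), format(x$n_permutations)
  ))
  invisible(x)
}

# all n! permutations of 1:n as rows (n <= 7)
perm_all <- function(n) {
  if (n > 7) stop("exhaustive enumeration limited to n <= 7", call. = FALSE)
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- perm_all(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# permutation matrix: either n_permutations random rows or all n! rows
perm_rows <- function(n, n_permutations, exhaustive, rng) {
  if (exhaustive) {
    return(perm_all(n))
  }
  t(vapply(seq_len(n_permutations), function(i) rng(sample.int(n)), integer(n)))
}

perm_pvalue <- function(obs, null, exhaustive, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  hits <- if (direction == "ge") sum(null >= obs - 1e-12) else sum(null <= obs + 1e-12)
  if (exhaustive) hits / length(null) else (hits + 1) / (length(null) + 1)
}

check_groups <- function(groups, min_size = 2, allow_singletons = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (!allow_singletons && any(sizes < min_size)) {
    stop(sprintf("every group needs at least %d samples", min_size), call. = FALSE)
  }
  groups
}

# ---- Kruskal-Wallis with multiple comparisons -------------------------------

kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  sizes <- tabulate(groups)
  h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) 0 else h / corr # all observations tied: H defined as 0
}

#' Kruskal-Wallis test with rank-based multiple comparisons
#'
#' Tie-corrected H with a chi-square p-value (default) or an exact p-value by
#' full enumeration of group assignments (`exact = TRUE`, small samples
#' only). Pairwise comparisons use the rank-based critical-difference
#' procedure: mean-rank differences are compared against a normal critical
#' value with tie-corrected variance, Bonferroni-adjusted across the k(k-1)/2
#' pairs.
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 groups of >= 2).
#' @param alpha Family significance level for the pairwise comparisons.
#' @param exact Compute the p-value by exhaustive enumeration of all distinct
#'   assignments of the observations to groups.
#' @return A `permutation_test` with `statistic` H, `p_value`, and a
#'   `pairwise` tibble (group1, group2, mean_rank_diff, critical_diff,
#'   significant).
#' @export
kruskal_multi <- function(values, groups, alpha = 0.05, exact = FALSE) {
  groups <- check_groups(groups)
  h <- kw_h(values, groups)
  k <- nlevels(groups)
  n <- length(values)
  p <- if (exact) {
    perms <- perm_all(n)
    null <- apply(perms, 1, function(ix) kw_h(values[ix], groups))
    mean(null >= h - 1e-12)
  } else {
    stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  }
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  sizes <- tabulate(groups)
  ties <- table(values)
  var_term <- (n * (n + 1) / 12) - sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(k, 2)
  zc <- stats::qnorm(1 - alpha / (k * (k - 1)))
  pw <- tibble::tibble(
    group1 = levels(groups)[pairs[1, ]],
    group2 = levels(groups)[pairs[2, ]],
    mean_rank_diff = abs(rbar[pairs[1, ]] - rbar[pairs[2, ]]),
    critical_diff = zc * sqrt(var_term * (1 / sizes[pairs[1, ]] + 1 / sizes[pairs[2, ]]))
  )
  pw$significant <- pw$mean_rank_diff > pw$critical_diff
  new_permutation_test("kruskal_wallis", c(H = h), p,
    n_permutations = if (exact) factorial(n) else NA_integer_, seed = NA_integer_,
    extra = list(pairwise = pw, alpha = alpha)
  )
}

#' Spearman rank correlation screen
#'
#' Tie-corrected Spearman rho (Pearson correlation of ranks) for every
#' column pair of `x` and `y`, with the t-approximation p-value. Constant
#' columns give rho `NA` (flagged, not an error).
#'
#' @param x Data frame of numeric columns.
#' @param y Optional second data frame (defaults to `x`).
#' @return A tibble with `var1`, `var2`, `rho`, `p_value`, `n`.
#' @export
spearman_screen <- function(x, y = x) {
  x <- as.data.frame(x)
  y <- as.data.frame(y)
  grid <- expand.grid(var1 = names(x), var2 = names(y), stringsAsFactors = FALSE)
  res <- purrr::pmap_dfr(grid, function(var1, var2) {
    a <- x[[var1]]
    b <- y[[var2]]
    ok <- stats::complete.cases(a, b)
    a <- a[ok]
    b <- b[ok]
    n <- length(a)
    if (n < 4 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(tibble::tibble(var1 = var1, var2 = var2, rho = NA_real_, p_value = NA_real_, n = n))
    }
    rho <- stats::cor(rank(a), rank(b))
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    tibble::tibble(
      var1 = var1, var2 = var2, rho = rho,
      p_value = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE), n = n
    )
  })
  tibble::as_tibble(res)
}

# ---- Mantel and partial Mantel ----------------------------------------------

#' Mantel and partial Mantel tests
#'
#' Correlation between the lower triangles of two distance matrices; the
#' partial variant correlates the residuals of `a` and `b` after removing a
#' conditioning matrix by linear regression. Significance by jointly
#' permuting rows and columns of `a`.
#'
#' @param a,b `dist_matrix` objects with matching ids.
#' @param conditioning Optional third `dist_matrix` to partial out.
#' @param method `"pearson"` or `"spearman"` (ranks taken before any
#'   residualisation).
#' @param n_permutations Random permutations (ignored when `exhaustive`).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all n! label permutations (n <= 7).
#' @return A `permutation_test` with statistic r (one-sided upper p).
#' @export
mantel_test <- function(a, b, conditioning = NULL,
                        method = c("pearson", "spearman"),
                        n_permutations = 999, seed = 1L, exhaustive = FALSE) {
  method <- match.arg(method)
  if (!identical(rownames(a), rownames(b))) {
    stop("distance matrices must share ids", call. = FALSE)
  }
  if (!is.null(conditioning) && !identical(rownames(a), rownames(conditioning))) {
    stop("conditioning matrix ids mismatch", call. = FALSE)
  }
  am <- unclass(a)
  n <- nrow(am)
  tri <- lower.tri(am)
  xf <- if (method == "spearman") function(v) rank(v) else identity
  bv <- xf(unclass(b)[tri])
  cv <- if (is.null(conditioning)) NULL else xf(unclass(conditioning)[tri])
  bv_scale <- stats::sd(bv)
  if (!is.null(cv)) bv <- stats::resid(stats::lm(bv ~ cv))
  # a residual that is numerically zero (e.g. conditioning == b) carries no
  # signal: its correlation is defined as 0 rather than noise
  safe_cor <- function(x, y, x_scale, y_scale) {
    if (stats::sd(x) < 1e-10 * max(x_scale, 1) ||
      stats::sd(y) < 1e-10 * max(y_scale, 1)) {
      return(0)
    }
    stats::cor(x, y)
  }
  stat <- function(perm) {
    av <- xf(am[perm, perm][tri])
    av_scale <- stats::sd(av)
    if (!is.null(cv)) av <- stats::resid(stats::lm(av ~ cv))
    safe_cor(av, bv, av_scale, bv_scale)
  }
  r_obs <- stat(seq_len(n))
  rng <- local_rng(seed)
  perms <- perm_rows(n, n_permutations, exhaustive, rng)
  null <- apply(perms, 1, stat)
  p <- perm_pvalue(r_obs, null, exhaustive)
  new_permutation_test(
    if (is.null(conditioning)) "mantel" else "partial_mantel",
    c(r = r_obs), p,
    n_permutations = nrow(perms), seed = seed,
    extra = list(method = method)
  )
}

# ---- PERMANOVA --------------------------------------------------------------

permanova_f <- function(d2, groups_idx, n, a) {
  ssw <- 0
  for (ix in groups_idx) {
    ssw <- ssw + sum(d2[ix, ix]) / (2 * length(ix))
  }
  sst <- sum(d2) / (2 * n)
  ssb <- sst - ssw
  if (ssw == 0 && ssb == 0) {
    return(NaN)
  }
  (ssb / (a - 1)) / (ssw / (n - a))
}

#' PERMANOVA (one-factor Adonis test)
#'
#' Pseudo-F from sums of squared dissimilarities: SS_total = sum d^2 / N,
#' SS_within = sum of within-group d^2 / group size; F = (SSB/(a-1)) /
#' (SSW/(N-a)). Significance by permutation of the group labels.
#'
#' @param d A `dist_matrix`.
#' @param groups Group labels.
#' @param n_permutations Random permutations (ignored when `exhaustive`).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all n! label permutations (n <= 7).
#' @param allow_singletons Permit groups of size 1 (their within-SS is 0).
#' @return A `permutation_test` with statistic pseudo-F. Identical
#'   communities everywhere give F = NaN, flagged `degenerate`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1L,
                      exhaustive = FALSE, allow_singletons = FALSE) {
  groups <- check_groups(groups, allow_singletons = allow_singletons)
  d2 <- unclass(d)^2
  n <- nrow(d2)
  a <- nlevels(groups)
  gsplit <- split(seq_len(n), groups)
  f_obs <- permanova_f(d2, gsplit, n, a)
  if (is.nan(f_obs)) {
    return(new_permutation_test("permanova", c(pseudo_F = NaN), NA_real_,
      n_permutations = 0L, seed = seed, extra = list(degenerate = TRUE)
    ))
  }
  rng <- local_rng(seed)
  perms <- perm_rows(n, n_permutations, exhaustive, rng)
  null <- apply(perms, 1, function(ix) {
    permanova_f(d2, split(ix, groups), n, a)
  })
  p <- perm_pvalue(f_obs, null, exhaustive)
  new_permutation_test("permanova", c(pseudo_F = f_obs), p,
    n_permutations = nrow(perms), seed = seed,
    extra = list(degenerate = FALSE)
  )
}

# ---- ANOSIM -----------------------------------------------------------------

anosim_r <- function(rank_d, within_tri, n) {
  rb <- mean(rank_d[!within_tri])
  rw <- mean(rank_d[within_tri])
  (rb - rw) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4) on the
#' ranked dissimilarities; significance by label permutation.
#'
#' @inheritParams permanova
#' @return A `permutation_test` with statistic R in \[-1, 1\].
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = 1L,
                   exhaustive = FALSE) {
  groups <- check_groups(groups, allow_singletons = TRUE)
  m <- unclass(d)
  n <- nrow(m)
  tri <- lower.tri(m)
  rank_d <- rank(m[tri])
  gi <- as.integer(groups)
  same <- outer(gi, gi, "==")[tri]
  r_obs <- anosim_r(rank_d, same, n)
  rng <- local_rng(seed)
  perms <- perm_rows(n, n_permutations, exhaustive, rng)
  null <- apply(perms, 1, function(ix) {
    gp <- gi[ix] # relabelled samples
    anosim_r(rank_d, outer(gp, gp, "==")[tri], n)
  })
  p <- perm_pvalue(r_obs, null, exhaustive)
  new_permutation_test("anosim", c(R = r_obs), p,
    n_permutations = nrow(perms), seed = seed
  )
}

# ---- MRPP -------------------------------------------------------------------

mrpp_delta <- function(m, groups_idx, n) {
  delta <- 0
  for (ix in groups_idx) {
    ni <- length(ix)
    delta <- delta + (ni / n) * sum(m[ix, ix]) / (ni * (ni - 1))
  }
  delta
}

#' Multiple-response permutation procedure (MRPP)
#'
#' delta is the group-size-weighted (n_i / N) mean within-group distance;
#' A = 1 - delta / E\[delta under permutation\]; the p-value is the fraction
#' of permuted deltas at or below the observed one.
#'
#' @inheritParams permanova
#' @return A `permutation_test` with statistics delta and A.
#' @export
mrpp <- function(d, groups, n_permutations = 999, seed = 1L,
                 exhaustive = FALSE) {
  groups <- check_groups(groups, min_size = 2)
  m <- unclass(d)
  n <- nrow(m)
  gsplit <- split(seq_len(n), groups)
  delta_obs <- mrpp_delta(m, gsplit, n)
  rng <- local_rng(seed)
  perms <- perm_rows(n, n_permutations, exhaustive, rng)
  null <- apply(perms, 1, function(ix) mrpp_delta(m, split(ix, groups), n))
  a_stat <- 1 - delta_obs / mean(null)
  p <- perm_pvalue(delta_obs, null, exhaustive, direction = "le")
  new_permutation_test("mrpp", c(delta = delta_obs, A = a_stat), p,
    n_permutations = nrow(perms), seed = seed
  )
}

# ---- PERMDISP ---------------------------------------------------------------

# Anderson's PERMDISP embedding: principal coordinates keeping real
# (positive-eigenvalue) and imaginary (negative-eigenvalue) parts.
permdisp_embed <- function(m) {
  g <- double_centre(-0.5 * m^2)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values), 1e-300) * 1e-9
  pos <- e$values > tol
  neg <- e$values < -tol
  list(
    real = e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos)),
    imag = e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), sum(neg))
  )
}

centroid_distances <- function(emb, groups) {
  z <- numeric(length(groups))
  for (g in levels(groups)) {
    ix <- which(groups == g)
    cr <- colMeans(emb$real[ix, , drop = FALSE])
    ci <- colMeans(emb$imag[ix, , drop = FALSE])
    dr2 <- rowSums(sweep(emb$real[ix, , drop = FALSE], 2, cr)^2)
    di2 <- rowSums(sweep(emb$imag[ix, , drop = FALSE], 2, ci)^2)
    z[ix] <- sqrt(pmax(dr2 - di2, 0))
  }
  z
}

anova_f <- function(z, groups) {
  gm <- tapply(z, groups, mean)
  sizes <- tabulate(groups)
  ssb <- sum(sizes * (gm - mean(z))^2)
  ssw <- sum((z - gm[as.integer(groups)])^2)
  a <- nlevels(groups)
  (ssb / (a - 1)) / (ssw / (length(z) - a))
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Samples are embedded by principal coordinates keeping real and imaginary
#' parts (the standard negative-eigenvalue handling), each sample's distance
#' to its group centroid is computed, and the one-way ANOVA F on those
#' distances is tested by permutation. The permutation shuffles the sample
#' group labels and recomputes the distances to the permuted-group centroids,
#' so the test is exact under exchangeability of the samples (distances to a
#' shared centroid are correlated within a group, which makes shuffling the
#' distance values themselves conservative).
#'
#' @inheritParams permanova
#' @return A `permutation_test` with statistic F, plus `centroid_distances`
#'   (per-sample tibble) and `group_means` (mean distance-to-centroid per
#'   group). A single group is allowed descriptively (F and p are NA);
#'   singleton groups have dispersion 0 and are flagged.
#' @export
permdisp <- function(d, groups, n_permutations = 999, seed = 1L) {
  groups <- as.factor(groups)
  m <- unclass(d)
  emb <- permdisp_embed(m)
  z <- centroid_distances(emb, groups)
  sizes <- table(groups)
  group_means <- tibble::tibble(
    group = names(sizes), n = as.integer(sizes),
    mean_centroid_distance = as.numeric(tapply(z, groups, mean)),
    singleton = as.integer(sizes) == 1
  )
  per_sample <- tibble::tibble(
    sample_id = rownames(m), group = as.character(groups),
    centroid_distance = z
  )
  if (nlevels(groups) < 2) {
    return(new_permutation_test("permdisp", c(F = NA_real_), NA_real_,
      n_permutations = 0L, seed = seed,
      extra = list(centroid_distances = per_sample, group_means = group_means)
    ))
  }
  f_obs <- anova_f(z, groups)
  rng <- local_rng(seed)
  null <- vapply(seq_len(n_permutations), function(i) {
    gp <- groups[rng(sample.int(length(z)))]
    anova_f(centroid_distances(emb, gp), gp)
  }, numeric(1))
  p <- (sum(null >= f_obs - 1e-12) + 1) / (n_permutations + 1)
  new_permutation_test("permdisp", c(F = f_obs), p,
    n_permutations = n_permutations, seed = seed,
    extra = list(centroid_distances = per_sample, group_means = group_means)
  )
}
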