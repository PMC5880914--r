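#' Richness-conserving null communities from the regional species pool
#'
#' Raup-Crick-style randomisation: the regional pool is every OTU observed
#' across all samples; for each iteration and each sample a species set of
#' exactly the observed richness is drawn without replacement from the pool,
#' with selection probability proportional to each species' occupancy
#' frequency (default), equiprobably, or proportionally to total abundance.
#' The output is presence/absence.
#'
#' @param table An [otu_table()] (>= 2 samples, non-empty pool).
#' @param n_iterations Number of null communities per sample.
#' @param seed Integer seed; ensembles are bit-for-bit reproducible.
#' @param weights `"occupancy"` (default), `"uniform"`, or `"abundance"`.
#' @return A `null_ensemble`: `draws` (per-iteration lists of pool indices
#'   per sample), `pool` (OTU ids), `weights_used`, `richness`, `sample_ids`,
#'   `n_iterations`, `seed`. Materialise any iteration's presence/absence
#'   matrix with [null_incidence()].
#' @export
null_randomize <- function(table, n_iterations = 999, seed = 1L,
                           weights = c("occupancy", "uniform", "abundance")) {
  weights <- match.arg(weights)
  m <- unclass(table)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  pool <- which(colSums(m) > 0)
  if (length(pool) == 0) stop("empty regional species pool", call. = FALSE)
  w <- switch(weights,
    occupancy = colSums(m[, pool, drop = FALSE] > 0),
    uniform = rep(1, length(pool)),
    abundance = colSums(m[, pool, drop = FALSE])
  )
  rich <- rowSums(m > 0)
  if (any(rich > length(pool))) {
    stop("sample richness exceeds pool size", call. = FALSE)
  }
  rng <- local_rng(seed)
  np <- length(pool)
  draws <- rng(lapply(seq_len(n_iterations), function(it) {
    lapply(rich, function(k) {
      if (k == 0) integer(0) else sample.int(np, k, prob = w)
    })
  }))
  structure(
    list(
      draws = draws, pool = colnames(m)[pool], weights_used = weights,
      weight_values = w, richness = rich, sample_ids = rownames(m),
      n_iterations = n_iterations, seed = as.integer(seed)
    ),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(
    "<null_ensemble> %d iterations x %d samples, pool %d OTUs, %s weights, seed %d\n",
    x$n_iterations, length(x$sample_ids), length(x$pool), x$weights_used, x$seed
  ))
  invisible(x)
}

#' Presence/absence matrix of one null iteration
#'
#' @param ensemble A `null_ensemble`.
#' @param iteration Iteration index.
#' @param samples Optional subset of sample indices or ids.
#' @return A 0/1 matrix (samples x pool OTUs).
#' @export
null_incidence <- function(ensemble, iteration, samples = NULL) {
  idx <- seq_along(ensemble$sample_ids)
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, ensemble$sample_ids) else samples
  }
  a <- matrix(0, length(idx), length(ensemble$pool),
    dimnames = list(ensemble$sample_ids[idx], ensemble$pool)
  )
  it <- ensemble$draws[[iteration]]
  for (j in seq_along(idx)) {
    a[j, it[[idx[j]]]] <- 1
  }
  a
}

jaccard_similarity_incidence <- function(a) {
  shared <- tcrossprod(a)
  rich <- rowSums(a)
  union <- outer(rich, rich, "+") - shared
  shared / union # NaN where both samples are empty
}

#' Beta-deviation z-scores against a null ensemble
#'
#' For every sample pair, z = (J_obs - mean(J_null)) / sd(J_null), where J is
#' the presence/absence Jaccard similarity and the null distribution comes
#' from one shared ensemble. Beta-deviation is the pairwise beta-diversity
#' after controlling for alpha-diversity (richness) differences.
#'
#' @param table The observed [otu_table()].
#' @param ensemble A `null_ensemble` built from a table with the same
#'   samples.
#' @return A `beta_deviation`: `z` (a `dist_matrix` of kind deviation),
#'   `j_obs`, `j_exp`, `j_sd` matrices, `n_undefined` (pairs with zero null
#'   SD or empty samples, whose z is NA), `n_iterations`, `seed`.
#' @export
beta_deviation <- function(table, ensemble) {
  m <- unclass(table)
  if (!identical(rownames(m), ensemble$sample_ids)) {
    stop("ensemble was built for different samples", call. = FALSE)
  }
  n <- nrow(m)
  a_obs <- (m > 0) * 1
  j_obs <- jaccard_similarity_incidence(a_obs)
  k <- ensemble$n_iterations
  s1 <- matrix(0, n, n)
  s2 <- matrix(0, n, n)
  for (it in seq_len(k)) {
    j <- jaccard_similarity_incidence(null_incidence(ensemble, it))
    s1 <- s1 + j
    s2 <- s2 + j^2
  }
  j_exp <- s1 / k
  j_var <- pmax((s2 - k * j_exp^2) / (k - 1), 0)
  j_sd <- sqrt(j_var)
  z <- (j_obs - j_exp) / j_sd
  z[!is.finite(z)] <- NA_real_
  diag(z) <- 0
  z <- (z + t(z)) / 2
  undefined <- sum(is.na(lower_tri(z)))
  dimnames(z) <- dimnames(j_obs) <- dimnames(j_exp) <- dimnames(j_sd) <-
    list(rownames(m), rownames(m))
  zm <- z
  zm[is.na(zm)] <- 0 # container requires finite entries; NA pairs tracked separately
  structure(
    list(
      z = dist_matrix(zm, kind = "deviation"),
      z_raw = z, j_obs = j_obs, j_exp = j_exp, j_sd = j_sd,
      n_undefined = undefined, n_iterations = k, seed = ensemble$seed
    ),
    class = "beta_deviation"
  )
}

#' @export
print.beta_deviation <- function(x, ...) {
  zv <- lower_tri(x$z_raw)
  cat(sprintf(
    "<beta_deviation> %d pairs, mean z = %.3f (%d undefined), %d iterations\n",
    length(zv), mean(zv, na.rm = TRUE), x$n_undefined, x$n_iterations
  ))
  invisible(x)
}

#' PERMDISP comparison of observed versus null communities per group
#'
#' For each group (elevational site) with at least 3 samples, the observed
#' members are pooled with a matched, equally sized set of null communities
#' (one ensemble iteration of the same samples), Jaccard distances are
#' computed over the pooled set, and PERMDISP distance-to-centroid values are
#' compared between observed and null with an F statistic and a paired
#' permutation p-value: each sample's observed and null community share its
#' richness, so the permutation independently swaps the two members of each
#' such pair and recomputes the centroid distances (a free relabelling would
#' break the richness pairing and be badly miscalibrated). Under
#' environmental filtering the observed mean distance-to-centroid falls below
#' the null one.
#'
#' @param table The observed [otu_table()].
#' @param ensemble A matching `null_ensemble`.
#' @param groups Group labels aligned with the table's samples.
#' @param n_permutations Permutations for each group's test.
#' @param seed Integer seed (chooses the matched iteration and permutations).
#' @return A tibble with one row per tested group: `group`, `n`,
#'   `observed_centroid`, `null_centroid`, `F`, `p_value`. Groups smaller
#'   than 3 are skipped with a warning.
#' @export
null_permdisp_test <- function(table, ensemble, groups, n_permutations = 999,
                               seed = 1L) {
  m <- unclass(table)
  if (!identical(rownames(m), ensemble$sample_ids)) {
    stop("ensemble was built for different samples", call. = FALSE)
  }
  groups <- as.factor(groups)
  rng <- local_rng(seed)
  rows <- list()
  for (g in levels(groups)) {
    ix <- which(groups == g)
    if (length(ix) < 3) {
      warning(sprintf("group '%s' has fewer than 3 samples; skipped", g))
      next
    }
    it <- rng(sample.int(ensemble$n_iterations, 1))
    a_obs <- (m[ix, ensemble$pool, drop = FALSE] > 0) * 1
    a_null <- null_incidence(ensemble, it, samples = ix)
    combined <- rbind(a_obs, a_null)
    jd <- 1 - jaccard_similarity_incidence(combined)
    jd[!is.finite(jd)] <- 0
    diag(jd) <- 0
    lab <- factor(rep(c("observed", "null"), each = length(ix)),
      levels = c("observed", "null")
    )
    emb <- permdisp_embed(jd)
    z <- centroid_distances(emb, lab)
    f_obs <- anova_f(z, lab)
    ng <- length(ix)
    null_f <- vapply(seq_len(n_permutations), function(i) {
      swap <- rng(sample(c(FALSE, TRUE), ng, replace = TRUE))
      lp <- lab
      lp[seq_len(ng)][swap] <- "null"
      lp[ng + seq_len(ng)][swap] <- "observed"
      anova_f(centroid_distances(emb, lp), lp)
    }, numeric(1))
    p <- (sum(null_f >= f_obs - 1e-12) + 1) / (n_permutations + 1)
    rows[[g]] <- tibble::tibble(
      group = g, n = length(ix),
      observed_centroid = mean(z[lab == "observed"]),
      null_centroid = mean(z[lab == "null"]),
      F = f_obs, p_value = p
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  out
}
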