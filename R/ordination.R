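#' Principal coordinates analysis
#'
#' Eigen-decomposition of the double-centred -0.5 * D^2 matrix. Axes are
#' returned for positive eigenvalues only; negative eigenvalues (from
#' non-Euclidean dissimilarities) are reported but their axes discarded (no
#' Lingoes/Cailliez correction by default).
#'
#' @param d A `dist_matrix` of kind dissimilarity.
#' @param correction `"none"` (default) or `"cailliez"` (adds the constant
#'   that makes all eigenvalues non-negative).
#' @return An object of class `pcoa_result`: `points` (samples x positive
#'   axes, scaled by sqrt eigenvalue), `eigenvalues` (all, non-increasing),
#'   `negative_magnitude` (sum of |negative eigenvalues|), `ids`.
#' @export
pcoa <- function(d, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  if (dm_kind(d) != "dissimilarity") {
    stop("pcoa requires a dissimilarity matrix", call. = FALSE)
  }
  m <- unclass(d)
  if (correction == "cailliez" && nrow(m) > 2) {
    m <- m + cailliez_constant(m) * (1 - diag(nrow(m)))
  }
  g <- double_centre(-0.5 * m^2)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values), 0) * 1e-9
  pos <- e$values > tol
  pts <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  rownames(pts) <- rownames(m)
  if (sum(pos) > 0) colnames(pts) <- paste0("PCoA", seq_len(sum(pos)))
  structure(
    list(
      points = pts, eigenvalues = e$values, vectors = e$vectors,
      negative_magnitude = sum(abs(e$values[e$values < -tol])),
      ids = rownames(m)
    ),
    class = "pcoa_result"
  )
}

double_centre <- function(a) {
  rm <- rowMeans(a)
  cm <- colMeans(a)
  a - outer(rm, rep(1, ncol(a))) - outer(rep(1, nrow(a)), cm) + mean(a)
}

# smallest constant c such that D + c (off-diagonal) is Euclidean
cailliez_constant <- function(m) {
  n <- nrow(m)
  g1 <- double_centre(-0.5 * m^2)
  g2 <- double_centre(-0.5 * m)
  zero <- matrix(0, n, n)
  b <- rbind(cbind(zero, 2 * g1), cbind(-diag(n), -4 * g2))
  max(Re(eigen(b, only.values = TRUE)$values))
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf(
    "<pcoa_result> %d samples, %d positive axes (negative magnitude %.3g)\n",
    length(x$ids), ncol(x$points), x$negative_magnitude
  ))
  invisible(x)
}

#' Kruskal stress-1 of a configuration against a dissimilarity matrix
#'
#' Monotone (isotonic) regression of configuration distances on the
#' dissimilarity order with primary tie handling, then
#' sqrt(sum((d - dhat)^2) / sum(d^2)).
#'
#' @param d A `dist_matrix`.
#' @param config Numeric samples x k configuration.
#' @return Stress-1 value.
#' @export
nmds_stress <- function(d, config) {
  delta <- lower_tri(unclass(d))
  dvec <- lower_tri(as.matrix(stats::dist(config)))
  ord <- order(delta, dvec)
  dhat <- numeric(length(dvec))
  dhat[ord] <- stats::isoreg(dvec[ord])$yf
  sqrt(sum((dvec - dhat)^2) / sum(dvec^2))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimised by alternating monotone regression (primary
#' tie handling) and Guttman-transform configuration updates, from one PCoA
#' start plus `n_starts` random starts; the best configuration is returned,
#' centred, rotated to principal axes, and scaled to unit root-mean-square.
#'
#' @param d A `dist_matrix` of kind dissimilarity.
#' @param k Number of dimensions (default 2).
#' @param n_starts Random starts in addition to the PCoA start.
#' @param max_iter Maximum iterations per start.
#' @param tol Convergence threshold on the change in stress.
#' @param seed Integer seed for the random starts.
#' @return An `nmds_result`: `points` (samples x k, axes NMDS1..NMDSk),
#'   `stress`, `n_starts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 300, tol = 1e-7, seed = 1L) {
  m <- unclass(d)
  n <- nrow(m)
  if (k >= n) stop("k must be smaller than the number of samples", call. = FALSE)
  rng <- local_rng(seed)
  delta <- lower_tri(m)
  li <- which(lower.tri(m), arr.ind = TRUE)

  run_one <- function(x0) {
    x <- x0
    dm_full <- as.matrix(stats::dist(x))
    stress_old <- Inf
    for (it in seq_len(max_iter)) {
      dvec <- dm_full[lower.tri(dm_full)]
      ord <- order(delta, dvec)
      dhat <- numeric(length(dvec))
      dhat[ord] <- stats::isoreg(dvec[ord])$yf
      stress <- sqrt(sum((dvec - dhat)^2) / sum(dvec^2))
      if (is.nan(stress) || abs(stress_old - stress) < tol) break
      stress_old <- stress
      # Guttman transform with target distances dhat
      ratio <- ifelse(dvec > 0, dhat / dvec, 0)
      b <- matrix(0, n, n)
      b[cbind(li[, 1], li[, 2])] <- -ratio
      b <- b + t(b)
      diag(b) <- -rowSums(b)
      x <- (b %*% x) / n
      dm_full <- as.matrix(stats::dist(x))
    }
    list(x = x, stress = nmds_stress(d, x))
  }

  starts <- c(
    list(pcoa_start(m, k)),
    lapply(seq_len(n_starts), function(i) {
      matrix(rng(stats::rnorm(n * k)), n, k)
    })
  )
  fits <- lapply(starts, run_one)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  x <- scale(best$x, scale = FALSE)
  x <- x %*% svd(x)$v # principal-axis rotation
  x <- x / sqrt(mean(rowSums(x^2)))
  dimnames(x) <- list(rownames(m), paste0("NMDS", seq_len(k)))
  structure(
    list(points = x, stress = nmds_stress(d, x), k = k, n_starts = n_starts, seed = seed),
    class = "nmds_result"
  )
}

pcoa_start <- function(m, k) {
  p <- pcoa(dist_matrix(m))$points
  if (ncol(p) >= k) {
    return(p[, seq_len(k), drop = FALSE])
  }
  cbind(p, matrix(stats::rnorm(nrow(m) * (k - ncol(p)), sd = 1e-4), nrow(m)))
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("<nmds_result> k = %d, stress = %.4f\n", x$k, x$stress))
  invisible(x)
}

#' Canonical correspondence analysis
#'
#' Chi-square-standardised community matrix regressed on row-weighted,
#' standardised predictors; the eigen-decomposition of the fitted values
#' gives the constrained axes. Total inertia equals the matrix chi-square
#' statistic divided by the grand total.
#'
#' @param table An [otu_table()] with positive row and column sums.
#' @param predictors Data frame of per-sample predictors (numeric or factor);
#'   constant predictors are an error.
#' @return A `cca_result`: `eigenvalues` (constrained), `total_inertia`,
#'   `constrained_inertia`, `site_scores`.
#' @export
cca <- function(table, predictors) {
  f <- unclass(table)
  storage.mode(f) <- "double"
  if (any(rowSums(f) == 0) || any(colSums(f) == 0)) {
    stop("table must have positive row and column sums", call. = FALSE)
  }
  predictors <- as.data.frame(predictors)
  if (any(vapply(predictors, function(v) length(unique(v)) == 1, logical(1)))) {
    stop("constant predictor", call. = FALSE)
  }
  p <- f / sum(f)
  r <- rowSums(p)
  cc <- colSums(p)
  qbar <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  total_inertia <- sum(qbar^2)

  x <- stats::model.matrix(~., data = predictors)[, -1, drop = FALSE]
  # weighted centring and standardisation, then sqrt(r) row weighting
  xc <- sweep(x, 2, colSums(x * r), "-")
  sdw <- sqrt(colSums(xc^2 * r))
  xc <- sweep(xc, 2, ifelse(sdw > 0, sdw, 1), "/")
  xw <- xc * sqrt(r)
  qr_x <- qr(xw)
  fitted <- qr.fitted(qr_x, qbar)
  sv <- svd(fitted)
  eig <- sv$d^2
  keep <- eig > max(eig, 0) * 1e-9
  structure(
    list(
      eigenvalues = eig[keep],
      total_inertia = total_inertia,
      constrained_inertia = sum(fitted^2),
      site_scores = {
        s <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
        rownames(s) <- rownames(f)
        s
      }
    ),
    class = "cca_result"
  )
}

#' Distance-based redundancy analysis
#'
#' PCoA axes (positive eigenvalues) regressed on the predictors. Deviation
#' matrices are first reflected to dissimilarities via
#' [deviation_to_dissimilarity()]. R-squared is constrained / total inertia in
#' the positive-eigenvalue space; a permutation pseudo-F test is run when
#' `n_permutations > 0`.
#'
#' @param d A `dist_matrix` (dissimilarity or deviation kind).
#' @param predictors Data frame of per-sample predictors.
#' @param n_permutations Row permutations for the pseudo-F test (0 = none).
#' @param seed Integer seed.
#' @return A `dbrda_result` with `r_squared`, `adj_r_squared`,
#'   `constrained_inertia`, `total_inertia`, `rank` (predictor rank),
#'   `pseudo_f`, `p_value`, `eigenvalues` (constrained axes), `seed`.
#' @export
dbrda <- function(d, predictors, n_permutations = 0, seed = 1L) {
  d <- deviation_to_dissimilarity(d)
  y <- pcoa(d)$points
  n <- nrow(y)
  x <- stats::model.matrix(~., data = as.data.frame(predictors))[, -1, drop = FALSE]
  if (ncol(x) > n - 1) stop("more predictors than samples - 1", call. = FALSE)
  x <- scale(x, scale = FALSE)
  qr_x <- qr(x)
  q <- qr_x$rank
  total <- sum(y^2)
  fit_stats <- function(yy) {
    constrained <- sum(qr.fitted(qr_x, yy)^2)
    f <- (constrained / q) / ((total - constrained) / (n - 1 - q))
    c(constrained, f)
  }
  obs <- fit_stats(y)
  constrained <- obs[1]
  r2 <- constrained / total
  pval <- NA_real_
  if (n_permutations > 0) {
    rng <- local_rng(seed)
    fperm <- vapply(seq_len(n_permutations), function(i) {
      fit_stats(y[rng(sample.int(n)), , drop = FALSE])[2]
    }, numeric(1))
    pval <- (sum(fperm >= obs[2]) + 1) / (n_permutations + 1)
  }
  ev <- svd(qr.fitted(qr_x, y))$d^2
  structure(
    list(
      r_squared = r2,
      adj_r_squared = adjusted_r2(r2, n, q),
      constrained_inertia = constrained, total_inertia = total,
      rank = q, pseudo_f = obs[2], p_value = pval,
      n_permutations = n_permutations,
      eigenvalues = ev[ev > max(ev, 0) * 1e-9], seed = seed
    ),
    class = "dbrda_result"
  )
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf(
    "<dbrda_result> R2 = %.4f (adj %.4f), pseudo-F = %.3f, p = %s\n",
    x$r_squared, x$adj_r_squared, x$pseudo_f,
    ifelse(is.na(x$p_value), "NA", format(x$p_value))
  ))
  invisible(x)
}

#' Ezekiel-adjusted R-squared
#'
#' 1 - (1 - r2) (n - 1) / (n - p - 1).
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of samples.
#' @param p Number of predictors.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("n must exceed p + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# Prim's minimum spanning tree; returns the maximum edge weight.
mst_max_edge <- function(m) {
  n <- nrow(m)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- m[1, ]
  max_edge <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    max_edge <- max(max_edge, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, m[j, ])
  }
  max_edge
}

#' Principal coordinates of neighbour matrices (PCNM)
#'
#' Classical PCNM spatial eigenvectors: the truncation threshold t is the
#' longest edge of the minimum spanning tree of the locations; distances
#' beyond t are replaced by 4t; the truncated matrix is subjected to PCoA and
#' the orthonormal eigenvectors with positive eigenvalues returned.
#'
#' @param geo_km A `dist_matrix` of geographic distances (km).
#' @return A `pcnm_basis`: `vectors` (samples x k, orthonormal),
#'   `eigenvalues` (positive, non-increasing), `threshold_km`.
#' @export
pcnm <- function(geo_km) {
  m <- unclass(geo_km)
  if (nrow(m) < 2) stop("need at least 2 locations", call. = FALSE)
  if (all(m == 0)) stop("all locations identical", call. = FALSE)
  t_km <- mst_max_edge(m)
  dtr <- m
  dtr[dtr > t_km] <- 4 * t_km
  diag(dtr) <- 0
  g <- double_centre(-0.5 * dtr^2)
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  v <- e$vectors[, pos, drop = FALSE]
  dimnames(v) <- list(rownames(m), paste0("PCNM", seq_len(sum(pos))))
  structure(
    list(vectors = v, eigenvalues = e$values[pos], threshold_km = t_km),
    class = "pcnm_basis"
  )
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat(sprintf(
    "<pcnm_basis> %d eigenvectors, truncation threshold %.3f km\n",
    ncol(x$vectors), x$threshold_km
  ))
  invisible(x)
}
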