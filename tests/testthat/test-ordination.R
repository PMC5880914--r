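test_that("PCoA recovers Euclidean geometry exactly", {
  # collinear points at 0, 3, 4: a single positive axis
  pts <- matrix(c(0, 3, 4), 3)
  d <- euclid_dm(pts, ids = c("a", "b", "c"))
  p <- pcoa(d)
  expect_equal(sum(p$eigenvalues > 1e-8), 1)
  expect_equal(as.matrix(dist(p$points)), unclass(d),
    ignore_attr = TRUE, tolerance = 1e-10
  )

  set.seed(21)
  x <- matrix(rnorm(30), 10, 3)
  d2 <- euclid_dm(x)
  p2 <- pcoa(d2)
  expect_equal(as.matrix(dist(p2$points)), unclass(d2),
    ignore_attr = TRUE, tolerance = 1e-8
  )
  xc <- scale(x, scale = FALSE)
  expect_equal(sum(p2$eigenvalues[p2$eigenvalues > 0]), sum(xc^2), tolerance = 1e-8)
  expect_equal(p2$negative_magnitude, 0, tolerance = 1e-8)

  zero <- dist_matrix(matrix(0, 4, 4), ids = paste0("s", 1:4))
  pz <- pcoa(zero)
  expect_true(all(abs(pz$eigenvalues) < 1e-12))
  expect_equal(ncol(pz$points), 0)
})

test_that("PCoA eigenvalues are non-increasing and match an independent oracle", {
  tab <- rand_table(7, 25, seed = 8)
  d <- dissimilarity_matrix(tab, "bray_curtis")
  p <- pcoa(d)
  expect_true(all(diff(p$eigenvalues) <= 1e-10))
  # dense oracle: direct eigendecomposition with explicit centring matrix
  n <- nrow(d)
  h <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * h %*% unclass(d)^2 %*% h
  ev <- eigen((g + t(g)) / 2, symmetric = TRUE)$values
  expect_equal(p$eigenvalues, ev, tolerance = 1e-10)
})

test_that("NMDS embeds embeddable configurations at near-zero stress", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4), 3, 2, byrow = TRUE)
  d <- euclid_dm(pts, ids = c("a", "b", "c"))
  fit <- nmds(d, k = 2, n_starts = 5, seed = 2)
  expect_lt(fit$stress, 1e-4)
  expect_equal(colnames(fit$points), c("NMDS1", "NMDS2"))
  # centred, unit RMS
  expect_equal(colMeans(fit$points), c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-8)
  expect_equal(mean(rowSums(fit$points^2)), 1, tolerance = 1e-8)
})

test_that("stress-1 is invariant to rotation, reflection, and scaling", {
  set.seed(3)
  tab <- rand_table(8, 30, seed = 3)
  d <- dissimilarity_matrix(tab, "bray_curtis")
  cfg <- matrix(rnorm(16), 8, 2)
  s0 <- nmds_stress(d, cfg)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  expect_equal(nmds_stress(d, cfg %*% rot), s0, tolerance = 1e-12)
  expect_equal(nmds_stress(d, cfg %*% diag(c(-1, 1))), s0, tolerance = 1e-12)
  expect_equal(nmds_stress(d, 3.7 * cfg), s0, tolerance = 1e-12)
})

test_that("NMDS stress matches an independent optimiser on small problems", {
  set.seed(4)
  x <- matrix(rnorm(50), 10, 5)
  d <- euclid_dm(x)
  ours <- nmds(d, k = 2, n_starts = 20, seed = 5)
  oracle <- suppressMessages(vegan::metaMDS(as.dist(unclass(d)), k = 2, trace = 0))
  expect_equal(ours$stress, oracle$stress, tolerance = 1e-3)
  # tied dissimilarities only relax the monotone constraints
  dt <- unclass(d)
  dt[dt > median(dt)] <- round(dt[dt > median(dt)], 1) # introduce ties
  dtied <- dist_matrix((dt + t(dt)) / 2)
  fit_tied <- nmds(dtied, k = 2, n_starts = 10, seed = 6)
  expect_true(is.finite(fit_tied$stress))
})

test_that("CCA inertia equals the chi-square statistic and vegan's solution", {
  tab <- rand_table(6, 4, seed = 12, lambda = 6)
  m <- unclass(tab)
  storage.mode(m) <- "double"
  exp_m <- outer(rowSums(m), colSums(m)) / sum(m)
  chisq <- sum((m - exp_m)^2 / exp_m)
  env <- data.frame(x = c(1.2, 3.4, 2.2, 5.1, 4.4, 0.9))
  fit <- cca(tab, env)
  expect_equal(fit$total_inertia, chisq / sum(m), tolerance = 1e-10)
  ref <- vegan::cca(m ~ x, data = env)
  expect_equal(fit$constrained_inertia, unname(ref$CCA$tot.chi), tolerance = 1e-8)
  expect_equal(fit$eigenvalues[1], unname(ref$CCA$eig[1]), tolerance = 1e-8)
  expect_error(cca(tab, data.frame(k = rep(1, 6))), "constant")
})

test_that("dbRDA attains R2 = 1 on self-explaining predictors", {
  set.seed(14)
  y <- matrix(rnorm(12 * 3), 12, 3) # rank-3 response: 3 positive axes
  d <- euclid_dm(y)
  axes <- pcoa(d)$points
  fit <- dbrda(d, as.data.frame(axes))
  expect_gt(fit$r_squared, 1 - 1e-8)

  # Euclidean response exactly linear in one predictor
  x <- seq(0, 1, length.out = 8)
  dlin <- euclid_dm(matrix(2 * x, 8), ids = paste0("s", 1:8))
  fit2 <- dbrda(dlin, data.frame(x = x))
  expect_equal(fit2$r_squared, 1, tolerance = 1e-10)

  expect_error(
    dbrda(dlin, as.data.frame(matrix(rnorm(8 * 9), 8))),
    "more predictors"
  )
})

test_that("dbRDA R2 matches vegan's capscale on a Euclidean fixture", {
  set.seed(15)
  y <- matrix(rnorm(12 * 4), 12, 4)
  d <- euclid_dm(y)
  env <- data.frame(a = rnorm(12), b = rnorm(12))
  fit <- dbrda(d, env)
  ref <- vegan::capscale(as.dist(unclass(d)) ~ a + b, data = env)
  expect_equal(fit$r_squared, unname(vegan::RsquareAdj(ref)$r.squared),
    tolerance = 1e-8
  )
  expect_equal(fit$adj_r_squared, unname(vegan::RsquareAdj(ref)$adj.r.squared),
    tolerance = 1e-8
  )
})

test_that("dbRDA permutation test is calibrated on null data", {
  set.seed(16)
  rej <- vapply(1:120, function(i) {
    y <- matrix(rnorm(10 * 3), 10, 3)
    d <- euclid_dm(y)
    fit <- dbrda(d, data.frame(x = rnorm(10)), n_permutations = 99, seed = i)
    fit$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.0)
  expect_lt(mean(rej), 0.13)
})

test_that("adjusted R2 follows the Ezekiel formula", {
  expect_equal(adjusted_r2(0.5, 10, 1), 0.4375)
  expect_equal(adjusted_r2(1, 25, 7), 1)
  expect_lt(adjusted_r2(0, 10, 3), 0)
  expect_error(adjusted_r2(0.5, 4, 3), "exceed")
  for (r2 in c(0, 0.3, 0.8)) {
    expect_lte(adjusted_r2(r2, 20, 4), r2)
  }
})

test_that("PCNM truncation and eigenvectors match the dense oracle", {
  pts <- matrix(c(0, 1, 2, 3), 4)
  g <- euclid_dm(pts, ids = paste0("p", 1:4))
  b <- pcnm(g)
  expect_equal(b$threshold_km, 1)
  # dense oracle: truncate, double-centre with explicit H, eigendecompose
  m <- unclass(g)
  m[m > 1] <- 4
  h <- diag(4) - matrix(0.25, 4, 4)
  e <- eigen(h %*% (-0.5 * m^2) %*% h, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-8
  expect_equal(b$eigenvalues, e$values[keep], tolerance = 1e-10)
  for (j in seq_len(ncol(b$vectors))) {
    expect_equal(abs(b$vectors[, j]), abs(e$vectors[, j]),
      ignore_attr = TRUE, tolerance = 1e-8
    )
  }
  # orthonormality
  expect_equal(crossprod(b$vectors), diag(ncol(b$vectors)),
    ignore_attr = TRUE, tolerance = 1e-8
  )
})

test_that("PCNM edge cases: two points, duplicates, degenerate input", {
  two <- euclid_dm(matrix(c(0, 5), 2), ids = c("a", "b"))
  b2 <- pcnm(two)
  expect_lte(ncol(b2$vectors), 1)
  # a duplicated location leaves the MST threshold unchanged
  pts <- matrix(c(0, 1, 2, 3), 4)
  t1 <- pcnm(euclid_dm(pts, ids = paste0("p", 1:4)))$threshold_km
  pts_dup <- rbind(pts, 2)
  t2 <- pcnm(euclid_dm(pts_dup, ids = paste0("p", 1:5)))$threshold_km
  expect_equal(t1, t2)
  expect_error(pcnm(dist_matrix(matrix(0, 3, 3), ids = paste0("s", 1:3))), "identical")
})

test_that("PCNM matches vegan's construction", {
  set.seed(17)
  pts <- cbind(runif(9, 0, 10), runif(9, 0, 10))
  g <- euclid_dm(pts, ids = paste0("s", 1:9))
  ours <- pcnm(g)
  ref <- vegan::pcnm(stats::dist(pts))
  expect_equal(ours$threshold_km, ref$threshold, tolerance = 1e-10)
  expect_equal(length(ours$eigenvalues), sum(ref$values > 1e-8 * max(ref$values)))
  expect_equal(ours$eigenvalues, ref$values[seq_along(ours$eigenvalues)],
    tolerance = 1e-8
  )
})
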