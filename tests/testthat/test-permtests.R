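test_that("Kruskal-Wallis H matches hand computation and kruskal.test", {
  res <- kruskal_multi(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(unname(res$statistic["H"]), 2.4)

  # all observations equal: H defined as 0 under the full-tie convention
  res0 <- kruskal_multi(rep(5, 6), rep(c("a", "b"), 3))
  expect_equal(unname(res0$statistic["H"]), 0)

  set.seed(41)
  v <- c(rnorm(5), rnorm(5, 1), rnorm(4, 2))
  g <- rep(c("a", "b", "c"), c(5, 5, 4))
  ours <- kruskal_multi(v, g)
  ref <- kruskal.test(v, factor(g))
  expect_equal(unname(ours$statistic["H"]), unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  # with ties, the tie-corrected H still matches
  vt <- c(1, 1, 2, 3, 3, 3, 4, 5)
  gt <- rep(c("a", "b"), 4)
  expect_equal(
    unname(kruskal_multi(vt, gt)$statistic["H"]),
    unname(kruskal.test(vt, factor(gt))$statistic),
    tolerance = 1e-12
  )
  expect_error(kruskal_multi(1:3, c("a", "a", "b")), "at least 2")
})

test_that("exact Kruskal-Wallis p equals exhaustive rank-assignment enumeration", {
  v <- c(1.2, 3.4, 0.7, 2.2, 5.1, 4.4, 2.9)
  g <- rep(c("a", "b", "c"), c(3, 2, 2))
  ours <- kruskal_multi(v, g, exact = TRUE)
  # independent oracle: enumerate assignments by choosing positions per group
  h_of <- function(vals, grp) {
    k <- kruskal.test(vals, factor(grp))
    unname(k$statistic)
  }
  h_obs <- h_of(v, g)
  count <- 0
  total <- 0
  for (ix_a in utils::combn(7, 3, simplify = FALSE)) {
    rest <- setdiff(1:7, ix_a)
    for (ix_b in utils::combn(rest, 2, simplify = FALSE)) {
      ix_c <- setdiff(rest, ix_b)
      grp <- integer(7)
      grp[ix_a] <- 1
      grp[ix_b] <- 2
      grp[ix_c] <- 3
      total <- total + 1
      if (h_of(v, grp) >= h_obs - 1e-12) count <- count + 1
    }
  }
  expect_equal(ours$p_value, count / total, tolerance = 1e-12)
})

test_that("rank-based multiple comparisons flag the separated group", {
  v <- c(1, 2, 3, 2, 3, 4, 50, 60, 70)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_multi(v, g, alpha = 0.05)
  pw <- res$pairwise
  expect_true(pw$significant[pw$group1 == "a" & pw$group2 == "c"])
  expect_false(pw$significant[pw$group1 == "a" & pw$group2 == "b"])
})

test_that("Spearman screen matches the rank-then-Pearson definition", {
  x <- data.frame(up = 1:10, noise = rnorm(10))
  y <- data.frame(inc = (1:10)^2, dec = -(1:10)^3)
  res <- spearman_screen(x, y)
  expect_equal(res$rho[res$var1 == "up" & res$var2 == "inc"], 1)
  expect_equal(res$rho[res$var1 == "up" & res$var2 == "dec"], -1)

  set.seed(42)
  a <- rnorm(20)
  b <- a + rnorm(20)
  r <- spearman_screen(data.frame(a = a), data.frame(b = b))
  expect_equal(r$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
  ref <- cor.test(a, b, method = "spearman")
  expect_equal(r$rho, unname(ref$estimate), tolerance = 1e-12)

  const <- spearman_screen(data.frame(k = rep(1, 10)), data.frame(b = rnorm(10)))
  expect_true(is.na(const$rho))
  expect_true(is.na(const$p_value))
})

test_that("Mantel statistics satisfy their identities", {
  set.seed(43)
  a <- euclid_dm(matrix(rnorm(12), 6), ids = paste0("s", 1:6))
  b <- euclid_dm(matrix(rnorm(12), 6), ids = paste0("s", 1:6))
  expect_equal(unname(mantel_test(a, a, n_permutations = 9)$statistic["r"]), 1)
  pr <- mantel_test(a, b, conditioning = b, n_permutations = 9)
  expect_equal(unname(pr$statistic["r"]), 0, tolerance = 1e-10)
  bad <- euclid_dm(matrix(rnorm(12), 6), ids = paste0("x", 1:6))
  expect_error(mantel_test(a, bad), "share ids")
})

test_that("Mantel r and permutation p match vegan on random matrices", {
  set.seed(44)
  a <- euclid_dm(matrix(rnorm(20), 10), ids = paste0("s", 1:10))
  b <- euclid_dm(matrix(rnorm(20), 10), ids = paste0("s", 1:10))
  ours <- mantel_test(a, b, n_permutations = 999, seed = 9)
  ref <- vegan::mantel(as.dist(unclass(a)), as.dist(unclass(b)), permutations = 999)
  expect_equal(unname(ours$statistic["r"]), unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p_value - ref$signif), 0.1)
})

test_that("exhaustive Mantel p equals full label enumeration", {
  set.seed(45)
  a <- euclid_dm(matrix(rnorm(10), 5), ids = paste0("s", 1:5))
  b <- euclid_dm(matrix(rnorm(10), 5), ids = paste0("s", 1:5))
  ours <- mantel_test(a, b, exhaustive = TRUE)
  # oracle: enumerate all 5! = 120 permutations independently
  perms <- all_perms(5)
  am <- unclass(a)
  bv <- unclass(b)[lower.tri(unclass(b))]
  r_obs <- cor(am[lower.tri(am)], bv)
  null <- apply(perms, 1, function(p) {
    ap <- am[p, p]
    cor(ap[lower.tri(ap)], bv)
  })
  expect_equal(ours$p_value, mean(null >= r_obs - 1e-12))
  expect_equal(ours$n_permutations, 120)
})

test_that("PERMANOVA pseudo-F is exact on the hand-computed configuration", {
  # within-group distance 1, between-group distance 2, groups {1,2} and {3,4}
  m <- matrix(2, 4, 4)
  m[1, 2] <- m[2, 1] <- 1
  m[3, 4] <- m[4, 3] <- 1
  diag(m) <- 0
  d <- dist_matrix(m, ids = paste0("s", 1:4))
  res <- permanova(d, c("a", "a", "b", "b"), n_permutations = 99)
  expect_equal(unname(res$statistic["pseudo_F"]), 7.0)
})

test_that("PERMANOVA matches vegan::adonis2 and flags degenerate input", {
  tg <- two_group_dm(seed = 46)
  ours <- permanova(tg$d, tg$groups, n_permutations = 199, seed = 3)
  ref <- vegan::adonis2(as.dist(unclass(tg$d)) ~ g,
    data = data.frame(g = tg$groups), permutations = 199
  )
  expect_equal(unname(ours$statistic["pseudo_F"]), ref$F[1], tolerance = 1e-10)

  m0 <- matrix(0, 4, 4)
  d0 <- dist_matrix(m0, ids = paste0("s", 1:4))
  res0 <- permanova(d0, c("a", "a", "b", "b"))
  expect_true(res0$degenerate)
  expect_true(is.nan(res0$statistic["pseudo_F"]))
})

test_that("exhaustive PERMANOVA p equals full label enumeration", {
  tg <- two_group_dm(seed = 47, n_per = 3)
  ours <- permanova(tg$d, tg$groups, exhaustive = TRUE)
  perms <- all_perms(6)
  dmat <- unclass(tg$d)
  f_obs <- bf_permanova_f(dmat, tg$groups)
  null <- apply(perms, 1, function(p) bf_permanova_f(dmat[p, p], tg$groups))
  expect_equal(ours$p_value, mean(null >= f_obs - 1e-12))
})

test_that("ANOSIM attains R = 1 under complete separation and matches vegan", {
  tg <- two_group_dm(seed = 48, n_per = 4, shift = 50)
  res <- anosim(tg$d, tg$groups, n_permutations = 99, seed = 2)
  expect_equal(unname(res$statistic["R"]), 1)

  tg2 <- two_group_dm(seed = 49, n_per = 5, shift = 1)
  ours <- anosim(tg2$d, tg2$groups, n_permutations = 199, seed = 5)
  ref <- vegan::anosim(as.dist(unclass(tg2$d)), factor(tg2$groups), permutations = 199)
  expect_equal(unname(ours$statistic["R"]), unname(ref$statistic), tolerance = 1e-12)
})

test_that("exhaustive ANOSIM p equals full label enumeration", {
  tg <- two_group_dm(seed = 50, n_per = 3, shift = 1)
  ours <- anosim(tg$d, tg$groups, exhaustive = TRUE)
  perms <- all_perms(6)
  dmat <- unclass(tg$d)
  r_obs <- bf_anosim_r(dmat, tg$groups)
  null <- apply(perms, 1, function(p) bf_anosim_r(dmat, tg$groups[p]))
  expect_equal(ours$p_value, mean(null >= r_obs - 1e-12))
})

test_that("MRPP delta and A behave at the structural extremes", {
  m <- 0.7 * (1 - diag(6))
  d <- dist_matrix(m, ids = paste0("s", 1:6))
  res <- mrpp(d, rep(c("a", "b"), each = 3), n_permutations = 99)
  expect_equal(unname(res$statistic["delta"]), 0.7)
  expect_equal(unname(res$statistic["A"]), 0)

  # two tight clusters: all within-group distances 0
  m2 <- matrix(1, 6, 6)
  m2[1:3, 1:3] <- 0
  m2[4:6, 4:6] <- 0
  d2 <- dist_matrix(m2, ids = paste0("s", 1:6))
  res2 <- mrpp(d2, rep(c("a", "b"), each = 3), n_permutations = 99, seed = 4)
  expect_equal(unname(res2$statistic["delta"]), 0)
  expect_equal(unname(res2$statistic["A"]), 1)
  expect_error(mrpp(d2, c("a", rep("b", 5))), "at least 2")
})

test_that("MRPP matches vegan and its exhaustive null matches enumeration", {
  tg <- two_group_dm(seed = 51, n_per = 3, shift = 1.5)
  ours <- mrpp(tg$d, tg$groups, n_permutations = 199, seed = 6)
  ref <- vegan::mrpp(as.dist(unclass(tg$d)), factor(tg$groups), permutations = 199)
  expect_equal(unname(ours$statistic["delta"]), ref$delta, tolerance = 1e-12)
  # A depends on the permutation-estimated E[delta]: compare with absolute slack
  expect_lt(abs(unname(ours$statistic["A"]) - ref$A), 0.02)

  ex <- mrpp(tg$d, tg$groups, exhaustive = TRUE)
  perms <- all_perms(6)
  dmat <- unclass(tg$d)
  null <- apply(perms, 1, function(p) bf_mrpp_delta(dmat, tg$groups[p]))
  d_obs <- bf_mrpp_delta(dmat, tg$groups)
  expect_equal(ex$p_value, mean(null <= d_obs + 1e-12))
  expect_equal(unname(ex$statistic["A"]), 1 - d_obs / mean(null), tolerance = 1e-12)
})

test_that("PERMDISP centroid distances and F match direct computation", {
  # a group of identical samples has zero dispersion
  pts <- rbind(matrix(1.5, 3, 2), matrix(rnorm(6, 5), 3, 2))
  d <- euclid_dm(pts, ids = paste0("s", 1:6))
  res <- permdisp(d, rep(c("a", "b"), each = 3), n_permutations = 99)
  z <- res$centroid_distances$centroid_distance
  expect_equal(z[1:3], rep(0, 3), tolerance = 1e-10)

  # two points: each lies half the distance from the midpoint centroid
  d2 <- euclid_dm(matrix(c(0, 4), 2), ids = c("p", "q"))
  res2 <- permdisp(d2, c("g", "g"), n_permutations = 0)
  expect_equal(res2$centroid_distances$centroid_distance, c(2, 2))

  # constructed unequal spreads: F equals a direct one-way ANOVA on the
  # hand-computed Euclidean distances to group centroids
  set.seed(52)
  pts3 <- rbind(matrix(rnorm(8, sd = 0.3), 4, 2), matrix(rnorm(8, sd = 3), 4, 2))
  g3 <- rep(c("tight", "wide"), each = 4)
  d3 <- euclid_dm(pts3, ids = paste0("s", 1:8))
  res3 <- permdisp(d3, g3, n_permutations = 199, seed = 7)
  zc <- unlist(lapply(split(seq_len(8), g3), function(ix) {
    ctr <- colMeans(pts3[ix, ])
    sqrt(rowSums(sweep(pts3[ix, ], 2, ctr)^2))
  }))
  fit <- anova(lm(z ~ g, data.frame(z = zc, g = rep(c("tight", "wide"), each = 4))))
  expect_equal(unname(res3$statistic["F"]), fit$`F value`[1], tolerance = 1e-8)
})

test_that("PERMDISP matches vegan::betadisper on non-Euclidean input", {
  tab <- rand_table(10, 25, seed = 53)
  d <- dissimilarity_matrix(tab, "bray_curtis")
  g <- rep(c("a", "b"), each = 5)
  ours <- permdisp(d, g, n_permutations = 199, seed = 8)
  bd <- vegan::betadisper(as.dist(unclass(d)), factor(g), type = "centroid")
  ref_f <- anova(bd)$`F value`[1]
  expect_equal(unname(ours$statistic["F"]), ref_f, tolerance = 1e-8)
  expect_equal(
    ours$centroid_distances$centroid_distance,
    unname(bd$distances),
    tolerance = 1e-8
  )
})

test_that("tests are invariant to consistent relabeling of samples", {
  tg <- two_group_dm(seed = 54, n_per = 4)
  perm <- sample(8)
  d2 <- dist_matrix(unclass(tg$d)[perm, perm])
  g2 <- tg$groups[perm]
  expect_equal(
    unname(permanova(tg$d, tg$groups, n_permutations = 9)$statistic["pseudo_F"]),
    unname(permanova(d2, g2, n_permutations = 9)$statistic["pseudo_F"]),
    tolerance = 1e-12
  )
  expect_equal(
    unname(anosim(tg$d, tg$groups, n_permutations = 9)$statistic["R"]),
    unname(anosim(d2, g2, n_permutations = 9)$statistic["R"]),
    tolerance = 1e-12
  )
  expect_equal(
    unname(mrpp(tg$d, tg$groups, n_permutations = 9)$statistic["delta"]),
    unname(mrpp(d2, g2, n_permutations = 9)$statistic["delta"]),
    tolerance = 1e-12
  )
})

test_that("permutation p-values use the add-one convention and never reach 0", {
  tg <- two_group_dm(seed = 55, n_per = 4, shift = 30)
  res <- permanova(tg$d, tg$groups, n_permutations = 999, seed = 1)
  # resolution 1/(m+1): p * 1000 is a whole count, bounded away from 0
  expect_equal(res$p_value * 1000, round(res$p_value * 1000), tolerance = 1e-9)
  expect_gte(res$p_value, 1 / 1000)
  expect_lte(res$p_value, 0.05)
  expect_gt(mantel_test(tg$d, tg$d, n_permutations = 99)$p_value, 0)
})
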