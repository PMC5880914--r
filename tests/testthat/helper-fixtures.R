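# Shared fixtures and independent oracles used across the suite.

tiny_counts <- function() {
  matrix(c(1L, 2L, 3L, 4L),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("s1", "s2"), c("o1", "o2"))
  )
}

valid_metadata <- function(n = 4) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    site_id = rep("A", n),
    elevation = seq(1800, 2000, length.out = n),
    latitude = 29.5 + seq_len(n) * 1e-3,
    longitude = rep(102, n),
    vegetation_type = "broadleaf",
    pH = seq(5, 6, length.out = n),
    TC = 5, TN = 0.5, NH4 = 10, NO3 = 5, conductivity = 100,
    T10 = 10, MAP = 1000, MAT = 8, PSR = 30, DB = 20, EB = 50, DC = 10
  )
}

euclid_dm <- function(points, ids = NULL) {
  m <- as.matrix(stats::dist(points))
  if (!is.null(ids)) dimnames(m) <- list(ids, ids)
  dist_matrix(m)
}

rand_table <- function(n, p, seed = 1, lambda = 3) {
  set.seed(seed)
  otu_table(matrix(stats::rpois(n * p, lambda), n, p,
    dimnames = list(paste0("s", 1:n), paste0("o", 1:p))
  ))
}

# independent permutation generator (iterative insertion; differs from the
# package's recursive construction)
all_perms <- function(n) {
  out <- matrix(1L, 1, 1)
  for (m in 2:n) {
    grown <- vector("list", m)
    for (pos in seq_len(m)) {
      grown[[pos]] <- cbind(
        out[, seq_len(pos - 1), drop = FALSE], m,
        out[, seq(pos, m - 1)[seq_len(m - pos)], drop = FALSE]
      )
    }
    out <- do.call(rbind, grown)
  }
  out
}

# brute-force PERMANOVA pseudo-F straight from its definition
bf_permanova_f <- function(dmat, groups) {
  groups <- as.factor(groups)
  n <- nrow(dmat)
  a <- nlevels(groups)
  sst <- sum(dmat[lower.tri(dmat)]^2) / n
  ssw <- 0
  for (g in levels(groups)) {
    ix <- which(groups == g)
    sub <- dmat[ix, ix]
    ssw <- ssw + sum(sub[lower.tri(sub)]^2) / length(ix)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

bf_anosim_r <- function(dmat, groups) {
  groups <- as.factor(groups)
  n <- nrow(dmat)
  tri <- lower.tri(dmat)
  rk <- rank(dmat[tri])
  same <- outer(as.integer(groups), as.integer(groups), "==")[tri]
  (mean(rk[!same]) - mean(rk[same])) / (n * (n - 1) / 4)
}

bf_mrpp_delta <- function(dmat, groups) {
  groups <- as.factor(groups)
  n <- nrow(dmat)
  delta <- 0
  for (g in levels(groups)) {
    ix <- which(groups == g)
    sub <- dmat[ix, ix]
    delta <- delta + length(ix) / n * mean(sub[lower.tri(sub)])
  }
  delta
}

# brute-force rooted Faith's PD: union of root-to-leaf edge sets
bf_pd <- function(tree, tips) {
  if (length(tips) == 0) {
    return(0)
  }
  root <- length(tree$tip.label) + 1
  edges_used <- integer(0)
  for (tip in match(tips, tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges_used <- union(edges_used, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[edges_used])
}

# small Euclidean-configuration community for cross-checks
two_group_dm <- function(seed = 1, n_per = 4, shift = 2) {
  set.seed(seed)
  pts <- rbind(
    matrix(rnorm(n_per * 2), n_per),
    matrix(rnorm(n_per * 2, mean = shift), n_per)
  )
  list(
    d = euclid_dm(pts, ids = paste0("s", seq_len(2 * n_per))),
    groups = rep(c("low", "high"), each = n_per),
    points = pts
  )
}
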