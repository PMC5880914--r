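#' Rarefy an OTU table to equal depth
#'
#' Each retained sample is subsampled without replacement to exactly `depth`
#' reads; samples with fewer than `depth` reads are dropped with a warning.
#'
#' @param table An [otu_table()].
#' @param depth Target reads per sample (>= 1).
#' @param seed Integer seed.
#' @return A rarefied [otu_table()] (possibly with fewer samples).
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  rng <- local_rng(seed)
  totals <- total_counts(table)
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sprintf(
      "dropping %d sample(s) below depth %d: %s",
      sum(!keep), depth, paste(sample_ids(table)[!keep], collapse = ", ")
    ))
  }
  m <- unclass(table)[keep, , drop = FALSE]
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (sum(x) == depth) next
    reads <- rep.int(seq_along(x), x)
    picked <- rng(sample(reads, depth))
    m[i, ] <- tabulate(picked, nbins = length(x))
  }
  otu_table(m)
}

#' Per-sample OTU richness
#'
#' @param table An [otu_table()].
#' @return A tibble with `sample_id` and `richness` (count of OTUs with
#'   non-zero reads).
#' @export
richness <- function(table) {
  tibble::tibble(
    sample_id = sample_ids(table),
    richness = as.integer(rowSums(unclass(table) > 0))
  )
}

# list, per tip label, of the edge indices on its path to the root
ancestor_edges <- function(tree) {
  n_tip <- length(tree$tip.label)
  parent_edge <- integer(max(tree$edge))
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- n_tip + 1L
  out <- vector("list", n_tip)
  for (tip in seq_len(n_tip)) {
    node <- tip
    path <- integer(0)
    while (node != root) {
      e <- parent_edge[node]
      path <- c(path, e)
      node <- tree$edge[e, 1]
    }
    out[[tip]] <- path
  }
  names(out) <- tree$tip.label
  out
}

#' Faith's phylogenetic diversity
#'
#' Rooted-PD convention: the PD of a sample is the total branch length of the
#' minimal subtree connecting its observed OTUs *and the root*, so a
#' single-taxon sample has PD equal to its root-to-tip path length. An empty
#' sample has PD 0.
#'
#' @param table An [otu_table()]; every observed OTU must be a tree leaf.
#' @param tree A rooted [ape::phylo] tree.
#' @return A tibble with `sample_id`, `richness` and `faith_pd`.
#' @export
faith_pd <- function(table, tree) {
  present <- colnames(table)[colSums(unclass(table) > 0) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0) {
    stop(
      "OTU(s) absent from tree: ", paste(utils::head(missing, 10), collapse = ", "),
      if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10)
    , call. = FALSE)
  }
  anc <- ancestor_edges(tree)
  lens <- tree$edge.length
  pd <- vapply(seq_len(nrow(table)), function(i) {
    tips <- colnames(table)[unclass(table)[i, ] > 0]
    if (length(tips) == 0) {
      return(0)
    }
    sum(lens[unique(unlist(anc[tips], use.names = FALSE))])
  }, numeric(1))
  tibble::tibble(
    sample_id = sample_ids(table),
    richness = as.integer(rowSums(unclass(table) > 0)),
    faith_pd = pd
  )
}

#' Alpha diversity (richness and Faith's PD)
#'
#' @param table An [otu_table()].
#' @param tree Optional rooted tree for Faith's PD.
#' @param depth Optional rarefaction depth applied first.
#' @param seed Seed for rarefaction.
#' @return A tibble of per-sample alpha diversity; records the rarefaction
#'   depth used in attribute `rarefaction_depth`.
#' @export
alpha_diversity <- function(table, tree = NULL, depth = NULL, seed = 1L) {
  if (!is.null(depth)) table <- rarefy(table, depth, seed = seed)
  out <- if (is.null(tree)) richness(table) else faith_pd(table, tree)
  attr(out, "rarefaction_depth") <- depth
  out
}

#' Pairwise community dissimilarities
#'
#' Three metrics are offered. `jaccard_binary` is 1 - |A n B| / |A u B| on
#' presence/absence. `bray_curtis` is sum|x - y| / sum(x + y) on relative
#' abundances. `jaccard_abundance` (the Ruzicka index) is
#' 1 - sum min(x, y) / sum max(x, y) on relative abundances.
#'
#' @param table An [otu_table()].
#' @param metric One of `"jaccard_binary"`, `"bray_curtis"`,
#'   `"jaccard_abundance"`.
#' @param empty_pairs For a pair of all-zero samples the dissimilarity is
#'   undefined: `"error"` (default) or `"zero"`.
#' @return A `dist_matrix` of kind dissimilarity, values in \[0, 1\].
#' @export
dissimilarity_matrix <- function(table,
                                 metric = c("jaccard_binary", "bray_curtis", "jaccard_abundance"),
                                 empty_pairs = c("error", "zero")) {
  metric <- match.arg(metric)
  empty_pairs <- match.arg(empty_pairs)
  m <- unclass(table)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  storage.mode(m) <- "double"
  totals <- rowSums(m)
  empty <- totals == 0
  if (metric == "jaccard_binary") {
    a <- (m > 0) * 1
    shared <- tcrossprod(a)
    nsp <- rowSums(a)
    union <- outer(nsp, nsp, "+") - shared
    d <- 1 - shared / union
  } else {
    rel <- m / ifelse(totals == 0, 1, totals)
    manh <- as.matrix(stats::dist(rel, method = "manhattan"))
    bc <- manh / 2 # rows sum to 1, so sum(x + y) = 2
    bc[empty, ] <- NaN
    bc[, empty] <- NaN
    d <- if (metric == "bray_curtis") bc else 2 * bc / (1 + bc)
  }
  undef <- !is.finite(d)
  diag(undef) <- FALSE
  if (any(undef)) {
    if (empty_pairs == "error") {
      stop("dissimilarity undefined for pair(s) of empty samples", call. = FALSE)
    }
    d[undef] <- 0
  }
  diag(d) <- 0
  d <- pmin(pmax(d, 0), 1)
  dist_matrix(d, ids = sample_ids(table))
}

#' Distance-decay of similarity per elevational section
#'
#' Ordinary least squares of pairwise community similarity (1 -
#' dissimilarity) on pairwise geographic distance, fitted separately within
#' the lower and higher elevational sections. Similarity and distance are
#' untransformed.
#'
#' @param community A `dist_matrix` of community dissimilarities (or a
#'   similarity matrix with `is_similarity = TRUE`).
#' @param geo_km A `dist_matrix` of geographic distances in km.
#' @param sections A [gradient_sections()] object.
#' @param is_similarity Set TRUE if `community` already holds similarities.
#' @return A tibble with one row per section: `section`, `slope` (similarity
#'   per km), `intercept`, `r_squared`, `n_pairs`.
#' @export
distance_decay <- function(community, geo_km, sections, is_similarity = FALSE) {
  if (!identical(rownames(community), rownames(geo_km))) {
    stop("community and geographic matrices must share ids", call. = FALSE)
  }
  fit_one <- function(ids, label) {
    if (length(ids) < 3) stop("section has fewer than 3 samples", call. = FALSE)
    cm <- unclass(community)[ids, ids]
    gm <- unclass(geo_km)[ids, ids]
    sim <- if (is_similarity) lower_tri(cm) else 1 - lower_tri(cm)
    dist <- lower_tri(gm)
    if (length(sim) < 3) stop("fewer than 3 pairs in section ", label, call. = FALSE)
    fit <- stats::lm(sim ~ dist)
    rss <- sum(stats::resid(fit)^2)
    tss <- sum((sim - mean(sim))^2)
    tibble::tibble(
      section = label,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = if (tss > 0) 1 - rss / tss else NaN,
      n_pairs = length(sim)
    )
  }
  dplyr::bind_rows(
    fit_one(sections$lower_ids, "lower"),
    fit_one(sections$higher_ids, "higher")
  )
}
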