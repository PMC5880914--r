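# Shared dbRDA kernel on a pre-computed PCoA representation: returns the
# unadjusted R-squared of the centred predictor matrix.
rda_fit <- function(y, x) {
  x <- scale(as.matrix(x), scale = FALSE)
  qr_x <- qr(x)
  list(qr = qr_x, rank = qr_x$rank, constrained = sum(qr.fitted(qr_x, y)^2))
}

adj_r2_of <- function(y, x, total = sum(y^2)) {
  if (is.null(x) || ncol(as.matrix(x)) == 0) {
    return(list(r2 = 0, adj = 0, rank = 0))
  }
  f <- rda_fit(y, x)
  r2 <- f$constrained / total
  list(r2 = r2, adj = adjusted_r2(r2, nrow(y), f$rank), rank = f$rank)
}

pcoa_axes <- function(d) {
  d <- deviation_to_dissimilarity(d)
  pcoa(d)$points
}

#' Forward selection of dbRDA predictors with double stopping
#'
#' Forward selection on a distance matrix response: at each step the
#' candidate with the largest adjusted-R-squared gain is added only if (i)
#' its marginal permutation p-value is at or below `alpha` and (ii) the
#' cumulative adjusted R-squared does not exceed the global adjusted
#' R-squared of the model with all candidates. A global pre-test is run
#' first: if the all-candidate model is not significant, the selection is
#' empty.
#'
#' @param d A `dist_matrix` (dissimilarity or deviation; deviations are
#'   reflected first).
#' @param candidates Data frame of candidate predictor columns.
#' @param alpha Entry significance level.
#' @param n_permutations Permutations for the marginal tests.
#' @param seed Integer seed (selection is permutation-seed reproducible).
#' @return A `forward_selection`: `selected` (character), `steps` tibble
#'   (variable, adj_r2_cum, p_value), `global_adj_r2`, `global_p`, `seed`.
#' @export
forward_select <- function(d, candidates, alpha = 0.05, n_permutations = 999,
                           seed = 1L) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  y <- pcoa_axes(d)
  n <- nrow(y)
  total <- sum(y^2)
  rng <- local_rng(seed)

  global <- adj_r2_of(y, candidates, total)
  gfit <- rda_fit(y, candidates)
  f_of <- function(constrained, rank) {
    (constrained / rank) / ((total - constrained) / (n - 1 - rank))
  }
  f_obs <- f_of(gfit$constrained, gfit$rank)
  xg <- scale(as.matrix(candidates), scale = FALSE)
  qrg <- qr(xg)
  fperm <- vapply(seq_len(n_permutations), function(i) {
    yp <- y[rng(sample.int(n)), , drop = FALSE]
    f_of(sum(qr.fitted(qrg, yp)^2), gfit$rank)
  }, numeric(1))
  global_p <- (sum(fperm >= f_obs) + 1) / (n_permutations + 1)

  steps <- tibble::tibble(
    variable = character(), adj_r2_cum = numeric(),
    p_value = numeric()
  )
  selected <- character(0)
  if (global_p <= alpha) {
    remaining <- names(candidates)
    adj_sel <- 0
    repeat {
      if (length(remaining) == 0) break
      adjs <- vapply(remaining, function(v) {
        adj_r2_of(y, candidates[c(selected, v)], total)$adj
      }, numeric(1))
      best <- remaining[which.max(adjs)]
      adj_new <- max(adjs)
      if (adj_new > global$adj + 1e-10) break
      # marginal permutation test of `best` given the current selection
      x_new <- scale(as.matrix(candidates[c(selected, best)]), scale = FALSE)
      qr_new <- qr(x_new)
      q_new <- qr_new$rank
      x_sel <- if (length(selected)) scale(as.matrix(candidates[selected]), scale = FALSE) else NULL
      qr_sel <- if (length(selected)) qr(x_sel) else NULL
      q_sel <- if (length(selected)) qr_sel$rank else 0
      df_add <- q_new - q_sel
      if (df_add < 1) break
      partial_f <- function(yy) {
        c_new <- sum(qr.fitted(qr_new, yy)^2)
        c_sel <- if (is.null(qr_sel)) 0 else sum(qr.fitted(qr_sel, yy)^2)
        ((c_new - c_sel) / df_add) / ((total - c_new) / (n - 1 - q_new))
      }
      fo <- partial_f(y)
      fp <- vapply(seq_len(n_permutations), function(i) {
        partial_f(y[rng(sample.int(n)), , drop = FALSE])
      }, numeric(1))
      p <- (sum(fp >= fo) + 1) / (n_permutations + 1)
      if (p > alpha) break
      selected <- c(selected, best)
      remaining <- setdiff(remaining, best)
      adj_sel <- adj_new
      steps <- dplyr::bind_rows(steps, tibble::tibble(
        variable = best, adj_r2_cum = adj_new, p_value = p
      ))
    }
  }
  structure(
    list(
      selected = selected, steps = steps,
      global_adj_r2 = global$adj, global_p = global_p, seed = seed
    ),
    class = "forward_selection"
  )
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf(
    "<forward_selection> %d variable(s) selected (global adj R2 %.4f, p %.4g)\n",
    length(x$selected), x$global_adj_r2, x$global_p
  ))
  if (length(x$selected)) print(x$steps)
  invisible(x)
}

pure_fractions <- function(y, env, space, total = sum(y^2)) {
  ab <- adj_r2_of(y, env, total)$adj
  bc <- adj_r2_of(y, space, total)$adj
  joint <- if ((is.null(env) || ncol(as.data.frame(env)) == 0)) {
    bc
  } else if (is.null(space) || ncol(as.data.frame(space)) == 0) {
    ab
  } else {
    adj_r2_of(y, cbind(as.data.frame(env), as.data.frame(space)), total)$adj
  }
  c(a = joint - bc, b = ab + bc - joint, c = joint - ab, d = 1 - joint)
}

#' Four-fraction variation partitioning on a distance matrix
#'
#' Decomposes the variation of a (deviation or dissimilarity) matrix into
#' pure environmental \[a\], spatially structured environmental \[b\], pure
#' spatial \[c\], and residual \[d\] fractions of adjusted R-squared, from
#' three dbRDA fits (env, space, joint). The identities a+b = adjR2(env),
#' b+c = adjR2(space), a+b+c = adjR2(joint) and a+b+c+d = 1 hold exactly.
#'
#' @param d A `dist_matrix`.
#' @param env Data frame of environmental predictor columns (may be empty).
#' @param space Data frame of spatial predictor columns (may be empty).
#' @return A `variation_partition`: `fractions` tibble (fraction, adj_r2),
#'   `env_adj_r2`, `space_adj_r2`, `joint_adj_r2`, plus the inputs used.
#' @export
variation_partition <- function(d, env, space) {
  env <- as.data.frame(env)
  space <- as.data.frame(space)
  y <- pcoa_axes(d)
  n <- nrow(y)
  p_joint <- ncol(env) + ncol(space)
  if (p_joint >= n - 1) stop("combined predictors must be fewer than samples - 1", call. = FALSE)
  fr <- pure_fractions(y, env, space)
  structure(
    list(
      fractions = tibble::tibble(
        fraction = c("a_pure_env", "b_shared", "c_pure_space", "d_residual"),
        adj_r2 = unname(fr)
      ),
      env_adj_r2 = unname(fr["a"] + fr["b"]),
      space_adj_r2 = unname(fr["b"] + fr["c"]),
      joint_adj_r2 = unname(fr["a"] + fr["b"] + fr["c"]),
      env_vars = names(env), space_vars = names(space)
    ),
    class = "variation_partition"
  )
}

#' @export
print.variation_partition <- function(x, ...) {
  cat("<variation_partition>\n")
  print(x$fractions)
  invisible(x)
}

#' Bootstrap test comparing pure environmental and pure spatial fractions
#'
#' Samples are resampled with replacement `n_bootstrap` times; the pure
#' fractions a (environment) and c (space) are recomputed on each resample of
#' the distance matrix and predictor rows, and the two-sided p-value is
#' 2 * min(P(a - c <= 0), P(a - c >= 0)) over replicates. Degenerate
#' resamples (too few distinct samples to fit the models) are redrawn, with
#' a capped number of retries.
#'
#' @inheritParams variation_partition
#' @param n_bootstrap Number of bootstrap replicates.
#' @param seed Integer seed (same seed, identical p).
#' @return A `bootstrap_fraction_test`: `p_value`, `observed_diff`,
#'   `observed_a`, `observed_c`, `replicates` tibble (a, c), `seed`.
#' @export
bootstrap_fraction_test <- function(d, env, space, n_bootstrap = 999, seed = 1L) {
  env <- as.data.frame(env)
  space <- as.data.frame(space)
  dmat <- unclass(deviation_to_dissimilarity(d))
  n <- nrow(dmat)
  if (n < 8) stop("need at least 8 samples", call. = FALSE)
  rng <- local_rng(seed)
  frac_of <- function(idx) {
    dsub <- dmat[idx, idx]
    g <- double_centre(-0.5 * dsub^2)
    e <- eigen(g, symmetric = TRUE)
    tol <- max(abs(e$values), 1e-300) * 1e-9
    pos <- e$values > tol
    if (!any(pos)) stop("degenerate resample")
    y <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
    fr <- pure_fractions(y, env[idx, , drop = FALSE], space[idx, , drop = FALSE])
    fr[c("a", "c")]
  }
  obs <- frac_of(seq_len(n))
  reps <- matrix(NA_real_, n_bootstrap, 2)
  for (b in seq_len(n_bootstrap)) {
    for (try in seq_len(100)) {
      idx <- rng(sample.int(n, replace = TRUE))
      ok <- length(unique(idx)) > ncol(env) + ncol(space) + 1
      val <- if (ok) tryCatch(frac_of(idx), error = function(e) NULL) else NULL
      if (!is.null(val)) {
        reps[b, ] <- val
        break
      }
    }
    if (anyNA(reps[b, ])) stop("could not draw a non-degenerate resample", call. = FALSE)
  }
  diffs <- reps[, 1] - reps[, 2]
  p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  structure(
    list(
      p_value = p, observed_diff = unname(obs["a"] - obs["c"]),
      observed_a = unname(obs["a"]), observed_c = unname(obs["c"]),
      replicates = tibble::tibble(a = reps[, 1], c = reps[, 2]),
      n_bootstrap = n_bootstrap, seed = seed
    ),
    class = "bootstrap_fraction_test"
  )
}

#' @export
print.bootstrap_fraction_test <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_fraction_test> a = %.4f, c = %.4f, diff = %.4f, p = %.4g (%d resamples)\n",
    x$observed_a, x$observed_c, x$observed_diff, x$p_value, x$n_bootstrap
  ))
  invisible(x)
}
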