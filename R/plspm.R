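#' Specify a PLS path model
#'
#' @param paths Square numeric matrix over the latent variables,
#'   `paths[to, from]` non-zero for a directed link `from -> to`; must be
#'   acyclic. Row/column names are the latent names.
#' @param blocks Named list mapping each latent to the character vector of
#'   its manifest (indicator) columns; every block must be non-empty.
#' @return A `plspm_model`.
#' @export
plspm_model <- function(paths, blocks) {
  p <- as.matrix(paths)
  if (is.null(rownames(p))) stop("path matrix needs latent names as dimnames", call. = FALSE)
  if (!identical(rownames(p), colnames(p))) stop("path matrix dimnames must match", call. = FALSE)
  if (is.null(topological_order(p != 0))) stop("path matrix is cyclic", call. = FALSE)
  if (!setequal(names(blocks), rownames(p))) {
    stop("blocks must be named by the latent variables", call. = FALSE)
  }
  if (any(lengths(blocks) == 0)) stop("every block must be non-empty", call. = FALSE)
  structure(list(paths = p, blocks = blocks[rownames(p)]), class = "plspm_model")
}

#' Default causal structure: climate -> plant -> soil -> community
#'
#' The inner model used for the elevational-gradient analysis: climate
#' influences plant and soil attributes, plants influence soil, and plant and
#' soil attributes influence the bacterial community (manifested by the two
#' NMDS axes).
#'
#' @param climate,plant,soil,community Manifest column names per block.
#' @return A [plspm_model()].
#' @export
elevation_path_model <- function(climate = c("MAT", "MAP"),
                                 plant = c("PSR", "DB"),
                                 soil = c("pH", "conductivity"),
                                 community = c("NMDS1", "NMDS2")) {
  lv <- c("climate", "plant", "soil", "community")
  p <- matrix(0, 4, 4, dimnames = list(lv, lv))
  p["plant", "climate"] <- 1
  p["soil", "climate"] <- 1
  p["soil", "plant"] <- 1
  p["community", "plant"] <- 1
  p["community", "soil"] <- 1
  plspm_model(p, list(
    climate = climate, plant = plant, soil = soil, community = community
  ))
}

plspm_core <- function(x_std, model, max_iter, tol) {
  lv <- rownames(model$paths)
  k <- length(lv)
  adj <- model$paths != 0
  blocks_ix <- lapply(model$blocks, function(cols) match(cols, colnames(x_std)))
  w <- lapply(blocks_ix, function(ix) rep(1, length(ix)))
  score_of <- function(w) {
    y <- vapply(seq_len(k), function(j) {
      s <- x_std[, blocks_ix[[j]], drop = FALSE] %*% w[[j]]
      drop(s) / stats::sd(s)
    }, numeric(nrow(x_std)))
    colnames(y) <- lv
    y
  }
  fix_sign <- function(w, y) {
    for (j in seq_len(k)) {
      if (sum(stats::cor(x_std[, blocks_ix[[j]], drop = FALSE], y[, j])) < 0) {
        w[[j]] <- -w[[j]]
      }
    }
    w
  }
  normalize <- function(w) {
    for (j in seq_len(k)) {
      s <- x_std[, blocks_ix[[j]], drop = FALSE] %*% w[[j]]
      w[[j]] <- w[[j]] / stats::sd(s)
    }
    w
  }
  w <- normalize(w)
  w <- fix_sign(w, score_of(w))
  iter <- 0
  repeat {
    iter <- iter + 1
    y <- score_of(w)
    # inner estimation, path weighting scheme
    z <- matrix(0, nrow(y), k)
    for (j in seq_len(k)) {
      e <- numeric(k)
      preds <- which(adj[j, ])
      succs <- which(adj[, j])
      if (length(preds) > 0) {
        e[preds] <- stats::coef(stats::lm(y[, j] ~ y[, preds, drop = FALSE]))[-1]
      }
      if (length(succs) > 0) {
        e[succs] <- stats::cor(y[, j], y[, succs, drop = FALSE])
      }
      z[, j] <- y %*% e
    }
    # outer estimation, mode A
    w_new <- lapply(seq_len(k), function(j) {
      drop(stats::cor(x_std[, blocks_ix[[j]], drop = FALSE], z[, j]))
    })
    w_new <- normalize(w_new)
    w_new <- fix_sign(w_new, score_of(w_new))
    w_prev <- w
    w <- w_new
    if (max(abs(unlist(w) - unlist(w_prev))) < tol) break
    if (iter >= max_iter) {
      stop(sprintf(
        "PLS-PM did not converge in %d iterations (last weight change %.3g)",
        max_iter, max(abs(unlist(w) - unlist(w_prev)))
      ), call. = FALSE)
    }
  }
  y <- score_of(w)
  y <- scale(y)[, , drop = FALSE] # exact mean 0, sd 1
  colnames(y) <- lv
  loadings <- lapply(seq_len(k), function(j) {
    drop(stats::cor(x_std[, blocks_ix[[j]], drop = FALSE], y[, j]))
  })
  names(loadings) <- lv
  endo <- which(rowSums(adj) > 0)
  path_rows <- list()
  r2 <- stats::setNames(numeric(length(endo)), lv[endo])
  for (j in endo) {
    preds <- which(adj[j, ])
    fit <- stats::lm(y[, j] ~ y[, preds, drop = FALSE])
    cf <- stats::coef(fit)[-1]
    r2[lv[j]] <- 1 - sum(stats::resid(fit)^2) / sum((y[, j] - mean(y[, j]))^2)
    path_rows[[lv[j]]] <- tibble::tibble(
      from = lv[preds], to = lv[j], estimate = unname(cf)
    )
  }
  list(
    weights = stats::setNames(w, lv), scores = y, loadings = loadings,
    paths = dplyr::bind_rows(path_rows), r_squared = r2, iterations = iter
  )
}

#' Fit a partial least squares path model
#'
#' Lohmoller's iterative algorithm with reflective (mode A) outer estimation
#' and the path weighting scheme for the inner estimate. Manifests are
#' globally standardised; latent scores are standardised weighted sums of
#' their block's manifests; path coefficients are OLS regressions of each
#' endogenous latent on its predecessors. Optional bootstrap resampling gives
#' standard errors and percentile confidence intervals for the paths.
#'
#' @param data Data frame containing every manifest column.
#' @param model A [plspm_model()].
#' @param max_iter Maximum outer-weight iterations.
#' @param tol Convergence threshold on the maximum absolute weight change.
#' @param n_boot Bootstrap resamples (0 = none).
#' @param seed Integer seed for the bootstrap.
#' @return A `plspm_fit` with `paths` (tibble: from, to, estimate, and when
#'   bootstrapped se, conf_low, conf_high, significant), `r_squared`,
#'   `gof`, `scores`, `loadings`, `communalities`, `weights`, `iterations`,
#'   `seed`.
#' @export
fit_plspm <- function(data, model, max_iter = 300, tol = 1e-7, n_boot = 0,
                      seed = 1L) {
  stopifnot(inherits(model, "plspm_model"))
  manifests <- unlist(model$blocks, use.names = FALSE)
  missing <- setdiff(manifests, names(data))
  if (length(missing) > 0) {
    stop("manifest column(s) not in data: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(data)[manifests])
  if (nrow(x) <= length(manifests)) {
    stop("need more samples than manifest variables", call. = FALSE)
  }
  for (b in names(model$blocks)) {
    cols <- model$blocks[[b]]
    if (length(cols) > 1) {
      r <- stats::cor(x[, cols])
      if (min(eigen(r, only.values = TRUE)$values) < 1e-8) {
        warning(sprintf("block '%s' is collinear", b))
      }
    }
  }
  x_std <- scale(x)
  core <- plspm_core(x_std, model, max_iter, tol)
  communalities <- unlist(core$loadings)^2
  gof_val <- sqrt(mean(communalities) * mean(core$r_squared))
  paths <- core$paths
  if (n_boot > 0) {
    rng <- local_rng(seed)
    boot <- matrix(NA_real_, n_boot, nrow(paths))
    n <- nrow(x)
    b <- 0
    while (b < n_boot) {
      idx <- rng(sample.int(n, replace = TRUE))
      fit_b <- tryCatch(
        plspm_core(scale(x[idx, , drop = FALSE]), model, max_iter, tol),
        error = function(e) NULL
      )
      if (is.null(fit_b)) next
      b <- b + 1
      boot[b, ] <- fit_b$paths$estimate
    }
    paths$se <- apply(boot, 2, stats::sd)
    ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
    paths$conf_low <- ci[1, ]
    paths$conf_high <- ci[2, ]
    paths$significant <- paths$conf_low > 0 | paths$conf_high < 0
  }
  structure(
    list(
      paths = paths, r_squared = core$r_squared, gof = gof_val,
      scores = core$scores, loadings = core$loadings,
      communalities = communalities, weights = core$weights,
      iterations = core$iterations, n_boot = n_boot, seed = seed,
      model = model
    ),
    class = "plspm_fit"
  )
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf(
    "<plspm_fit> GOF = %.3f, %d iterations%s\n", x$gof, x$iterations,
    if (x$n_boot > 0) sprintf(", %d bootstrap resamples", x$n_boot) else ""
  ))
  print(x$paths)
  cat("R2:", paste(sprintf("%s = %.3f", names(x$r_squared), x$r_squared), collapse = ", "), "\n")
  invisible(x)
}

#' Goodness of fit of a fitted PLS path model
#'
#' The square root of (mean communality across all manifests) x (mean
#' R-squared across the endogenous latents). Values above 0.7 are
#' conventionally deemed acceptable.
#'
#' @param model A `plspm_fit`.
#' @return The GOF value in \[0, 1\].
#' @export
gof <- function(model) {
  stopifnot(inherits(model, "plspm_fit"))
  if (length(model$r_squared) == 0) stop("model has no endogenous latent", call. = FALSE)
  sqrt(mean(model$communalities) * mean(model$r_squared))
}
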