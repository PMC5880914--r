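#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.permutation_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = names(x$statistic),
    value = unname(x$statistic),
    p_value = x$p_value,
    n_permutations = x$n_permutations
  )
}

#' @export
tidy.nmds_result <- function(x, ...) {
  tibble::as_tibble(x$points, rownames = "sample_id")
}

#' @export
glance.nmds_result <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, n_starts = x$n_starts, seed = x$seed)
}

#' @export
tidy.pcoa_result <- function(x, ...) {
  tibble::as_tibble(x$points, rownames = "sample_id")
}

#' @export
tidy.variation_partition <- function(x, ...) x$fractions

#' @export
tidy.plspm_fit <- function(x, ...) x$paths

#' @export
glance.plspm_fit <- function(x, ...) {
  tibble::tibble(
    gof = x$gof,
    mean_communality = mean(x$communalities),
    mean_r_squared = mean(x$r_squared),
    iterations = x$iterations,
    n_boot = x$n_boot
  )
}

#' @export
tidy.beta_deviation <- function(x, ...) {
  n <- nrow(x$z_raw)
  ij <- which(lower.tri(x$z_raw), arr.ind = TRUE)
  tibble::tibble(
    sample_1 = rownames(x$z_raw)[ij[, 1]],
    sample_2 = rownames(x$z_raw)[ij[, 2]],
    j_obs = x$j_obs[ij],
    j_exp = x$j_exp[ij],
    j_sd = x$j_sd[ij],
    z = x$z_raw[ij]
  )
}

#' @export
glance.dbrda_result <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
    pseudo_f = x$pseudo_f, p_value = x$p_value, rank = x$rank
  )
}

#' @export
autoplot.nmds_result <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$NMDS1, .data$NMDS2)) +
    ggplot2::geom_point(if (is.null(colour)) {
      NULL
    } else {
      ggplot2::aes(colour = .data$colour)
    }) +
    ggplot2::labs(
      caption = sprintf("stress = %.3f", object$stress),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  p
}

#' @export
autoplot.variation_partition <- function(object, ...) {
  ggplot2::ggplot(object$fractions, ggplot2::aes(.data$fraction, .data$adj_r2)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "adjusted R²") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.beta_deviation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$z)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "β-deviation (z)", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Plot distance-decay fits
#'
#' @param fits Tibble from [distance_decay()].
#' @return A ggplot of slope per section.
#' @export
plot_distance_decay <- function(fits) {
  ggplot2::ggplot(fits, ggplot2::aes(.data$section, .data$slope)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "similarity per km") +
    ggplot2::theme_minimal()
}
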