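#' Define a synthetic elevational-gradient scenario
#'
#' The generator emulates the sampling design of a subtropical mountain
#' transect: 12 sites at roughly 200 m elevational intervals between 1800 and
#' 4100 m, eight soil samples per site, a soil pH gradient spanning 3.53-7.23
#' that drops abruptly between 2600 and 2800 m, five vegetation types
#' arranged in elevational bands, and climate covariates that change
#' monotonically with elevation (MAP increasing, MAT and T10 decreasing).
#'
#' Community structure arises from three separable channels so that
#' downstream variation partitioning has a known ground truth: a Gaussian pH
#' niche per OTU (width `env_filter_strength`, smaller = stronger
#' environmental filtering), a multiplicative vegetation-type affinity, and
#' an exponential spatial kernel on great-circle distance.
#'
#' @param n_sites Number of elevational sites.
#' @param samples_per_site Soil samples per site.
#' @param elevation_range Metres, low and high end of the transect.
#' @param n_otus Number of OTUs in the regional pool.
#' @param ph_range Soil pH at the lowest and highest site.
#' @param ph_step_interval Elevation band (m) over which the abrupt pH drop
#'   occurs.
#' @param ph_step_values pH immediately before and after the step.
#' @param env_filter_strength Gaussian niche width in pH units; `Inf`
#'   disables environmental filtering.
#' @param vegetation_affinity Relative abundance multiplier an OTU receives
#'   in a non-preferred vegetation type; 1 disables the vegetation channel.
#' @param spatial_decay_range_km e-folding range of the spatial kernel; `Inf`
#'   disables spatial structure.
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters of the OTU
#'   base-abundance distribution.
#' @param depth Sequencing depth (reads per sample); uniform across samples
#'   unless `depth_jitter_sd > 0`.
#' @param depth_jitter_sd Standard deviation of a Gaussian jitter on depth
#'   (reads), to exercise rarefaction.
#' @param horizontal_extent_km Horizontal length of the transect (the study
#'   design spans about 7 km per elevational section).
#' @param noise_sd Global multiplier on all metadata noise scales; 0 gives
#'   deterministic covariates.
#' @param seed Integer seed recorded in the scenario.
#' @return A list of class `gradient_scenario`.
#' @export
gradient_scenario <- function(n_sites = 12, samples_per_site = 8,
                              elevation_range = c(1800, 4100),
                              n_otus = 1500,
                              ph_range = c(7.23, 3.53),
                              ph_step_interval = c(2600, 2800),
                              ph_step_values = c(6.4, 5.3),
                              env_filter_strength = 0.5,
                              vegetation_affinity = 0.4,
                              spatial_decay_range_km = 15,
                              abundance_meanlog = 0, abundance_sdlog = 1.2,
                              depth = 2000, depth_jitter_sd = 0,
                              horizontal_extent_km = 14,
                              noise_sd = 1, seed = 1L) {
  sc <- list(
    n_sites = n_sites, samples_per_site = samples_per_site,
    elevation_range = elevation_range, n_otus = n_otus,
    ph_range = ph_range, ph_step_interval = ph_step_interval,
    ph_step_values = ph_step_values,
    env_filter_strength = env_filter_strength,
    vegetation_affinity = vegetation_affinity,
    spatial_decay_range_km = spatial_decay_range_km,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    depth = depth, depth_jitter_sd = depth_jitter_sd,
    horizontal_extent_km = horizontal_extent_km,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  stopifnot(
    sc$n_sites >= 2, sc$samples_per_site >= 1,
    sc$env_filter_strength > 0, sc$n_otus >= 2, sc$depth >= 1,
    all(sc$ph_range > 0), all(sc$ph_range < 14)
  )
  class(sc) <- "gradient_scenario"
  sc
}

#' @export
print.gradient_scenario <- function(x, ...) {
  cat(sprintf(
    "<gradient_scenario> %d sites x %d samples, %d OTUs, %g-%g m, sigma_pH = %g\n",
    x$n_sites, x$samples_per_site, x$n_otus, x$elevation_range[1],
    x$elevation_range[2], x$env_filter_strength
  ))
  invisible(x)
}

# Piecewise-linear monotone pH profile with an abrupt step between the two
# step elevations; spans ph_range across the whole gradient.
ph_profile <- function(elevation, scenario) {
  e <- scenario$elevation_range
  s <- scenario$ph_step_interval
  knots_x <- c(e[1], s[1], s[2], e[2])
  knots_y <- c(
    scenario$ph_range[1], scenario$ph_step_values[1],
    scenario$ph_step_values[2], scenario$ph_range[2]
  )
  stats::approx(knots_x, knots_y, xout = elevation, rule = 2)$y
}

vegetation_bands <- c("broadleaf", "mixed_forest", "conifer", "alpine_shrub", "alpine_meadow")

vegetation_of <- function(elevation) {
  cut(elevation,
    breaks = c(-Inf, 2600, 2850, 3600, 3850, Inf),
    labels = vegetation_bands, right = FALSE
  )
}

#' Generate per-sample metadata for a scenario
#'
#' Site-level climate is a deterministic monotone function of elevation (MAP
#' increasing, MAT and T10 decreasing); soil chemistry and plant attributes
#' carry sample-level noise scaled by `scenario$noise_sd`. Sites are laid out
#' on a north-south transect of `horizontal_extent_km`.
#'
#' @param scenario A [gradient_scenario()].
#' @param seed Optional seed overriding `scenario$seed`.
#' @return A metadata tibble (one row per sample) passing
#'   [validate_metadata()].
#' @export
simulate_metadata <- function(scenario, seed = scenario$seed) {
  rng <- local_rng(seed)
  ns <- scenario$n_sites
  nps <- scenario$samples_per_site
  n <- ns * nps
  elev_site <- round(seq(scenario$elevation_range[1], scenario$elevation_range[2],
    length.out = ns
  ))
  site_id <- sprintf("S%02d", seq_len(ns))
  site <- rep(site_id, each = nps)
  elev <- rep(elev_site, each = nps)
  sample_id <- paste0(site, "_", rep(seq_len(nps), times = ns))

  # transect geometry: sites spread along latitude, plots jittered ~50 m
  lat0 <- 29.55
  lon0 <- 102.0
  km_per_deg_lat <- 110.574
  site_lat <- lat0 + (seq_len(ns) - 1) / (ns - 1) *
    scenario$horizontal_extent_km / km_per_deg_lat
  lat <- rep(site_lat, each = nps) +
    rng(stats::rnorm(n, 0, 0.05 / km_per_deg_lat))
  lon <- lon0 + rng(stats::rnorm(n, 0, 0.05 / (km_per_deg_lat * cos(lat0 * pi / 180))))

  nsd <- scenario$noise_sd
  de <- elev - scenario$elevation_range[1]
  ph <- ph_profile(elev, scenario) + rng(stats::rnorm(n, 0, 0.12 * nsd))
  ph <- pmin(pmax(ph, 0.2), 13.8)

  map <- 800 + 0.5 * de
  mat <- 12.7 - 0.0055 * de
  t10 <- 14.2 - 0.005 * de

  tc <- pmax(1 + 9 * de / 2300 + rng(stats::rnorm(n, 0, 2 * nsd)), 0.6)
  tn <- pmax(tc / 16 + rng(stats::rnorm(n, 0, 0.1 * nsd)), 0.08)
  nh4 <- pmax(5 + 25 * de / 2300 + rng(stats::rnorm(n, 0, 4 * nsd)), 0)
  no3 <- pmax(12 - 4 * de / 2300 + rng(stats::rnorm(n, 0, 3 * nsd)), 0)
  cond <- pmin(pmax(55 * (ph - 3) + rng(stats::rnorm(n, 0, 15 * nsd)), 0), 262)

  psr <- pmax(round(55 - 14 * de / 1000 + rng(stats::rnorm(n, 0, 2 * nsd))), 1)
  w_eb <- exp(-de / 600)
  w_db <- exp(-((elev - 2400)^2) / (2 * 400^2))
  w_dc <- exp(-((elev - 3000)^2) / (2 * 500^2))
  wsum <- w_eb + w_db + w_dc
  woody <- as.numeric(elev < 3850)
  clip_pct <- function(x) pmin(pmax(x, 0), 100)
  eb <- clip_pct(100 * w_eb / wsum * woody + rng(stats::rnorm(n, 0, 2 * nsd)) * woody)
  db <- clip_pct(100 * w_db / wsum * woody + rng(stats::rnorm(n, 0, 2 * nsd)) * woody)
  dc <- clip_pct(100 * w_dc / wsum * woody + rng(stats::rnorm(n, 0, 2 * nsd)) * woody)

  validate_metadata(tibble::tibble(
    sample_id = sample_id, site_id = site, elevation = elev,
    latitude = lat, longitude = lon,
    vegetation_type = as.character(vegetation_of(elev)),
    pH = ph, TC = pmin(tc, 100), TN = pmin(tn, 100),
    NH4 = nh4, NO3 = no3, conductivity = cond,
    T10 = t10, MAP = map, MAT = mat, PSR = psr,
    DB = db, EB = eb, DC = dc
  ))
}

# run expr with an isolated, seeded RNG stream
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    expr
  }
}

#' OTU niche parameters for a scenario
#'
#' Draws, per OTU: a lognormal base abundance, a pH optimum uniform over the
#' scenario's pH range, a preferred vegetation type, and a spatial "home"
#' position on the transect.
#' @param scenario A [gradient_scenario()].
#' @param seed Seed (defaults to `scenario$seed + 1`).
#' @return A tibble with one row per OTU.
#' @export
otu_niche_params <- function(scenario, seed = scenario$seed + 1L) {
  rng <- local_rng(seed)
  k <- scenario$n_otus
  ph_lo <- min(scenario$ph_range)
  ph_hi <- max(scenario$ph_range)
  tibble::tibble(
    otu_id = sprintf("OTU%04d", seq_len(k)),
    base_abundance = rng(stats::rlnorm(k, scenario$abundance_meanlog, scenario$abundance_sdlog)),
    ph_optimum = rng(stats::runif(k, ph_lo, ph_hi)),
    preferred_vegetation = rng(sample(vegetation_bands, k, replace = TRUE)),
    home_fraction = rng(stats::runif(k))
  )
}

#' Expected relative abundances under the niche model
#'
#' Deterministic mean model: base abundance x Gaussian pH niche x vegetation
#' affinity x exponential spatial kernel, row-normalised to relative
#' abundances. Identical metadata rows therefore receive identical expected
#' abundance vectors.
#'
#' @param scenario A [gradient_scenario()].
#' @param metadata Metadata from [simulate_metadata()].
#' @param params OTU niche parameters from [otu_niche_params()].
#' @return A samples x OTUs matrix of expected relative abundances.
#' @export
expected_abundance <- function(scenario, metadata, params) {
  sig <- scenario$env_filter_strength
  ph_term <- if (is.infinite(sig)) {
    matrix(1, nrow(metadata), nrow(params))
  } else {
    exp(-outer(metadata$pH, params$ph_optimum, "-")^2 / (2 * sig^2))
  }
  veg_term <- ifelse(
    outer(metadata$vegetation_type, params$preferred_vegetation, "=="),
    1, scenario$vegetation_affinity
  )
  if (is.infinite(scenario$spatial_decay_range_km)) {
    sp_term <- 1
  } else {
    km_per_deg_lat <- 110.574
    lat0 <- 29.55
    home_lat <- lat0 + params$home_fraction * scenario$horizontal_extent_km / km_per_deg_lat
    dist_km <- geosphere::distHaversine(
      cbind(rep(102.0, nrow(metadata))[row(ph_term)], metadata$latitude[row(ph_term)]),
      cbind(102.0, home_lat[col(ph_term)]),
      r = 6371000
    ) / 1000
    sp_term <- matrix(exp(-dist_km / scenario$spatial_decay_range_km),
      nrow(metadata), nrow(params)
    )
  }
  e <- sweep(ph_term * veg_term * sp_term, 2, params$base_abundance, "*")
  e <- e / rowSums(e)
  dimnames(e) <- list(metadata$sample_id, params$otu_id)
  e
}

#' Generate a community count table under the niche model
#'
#' Counts are drawn multinomially per sample at the scenario depth from the
#' [expected_abundance()] mean model, so each sample total equals its depth
#' exactly.
#'
#' @inheritParams expected_abundance
#' @param seed Seed (defaults to `scenario$seed + 2`).
#' @param params Optional pre-drawn [otu_niche_params()].
#' @return An [otu_table()]; the niche parameters used are attached as
#'   attribute `niche_params`.
#' @export
simulate_community <- function(scenario, metadata, params = NULL,
                               seed = scenario$seed + 2L) {
  if (scenario$depth < 1) stop("depth must be >= 1", call. = FALSE)
  rng <- local_rng(seed)
  if (is.null(params)) params <- otu_niche_params(scenario)
  e <- expected_abundance(scenario, metadata, params)
  n <- nrow(e)
  depth <- rep(scenario$depth, n)
  if (scenario$depth_jitter_sd > 0) {
    depth <- pmax(round(rng(stats::rnorm(n, scenario$depth, scenario$depth_jitter_sd))), 1)
  }
  counts <- matrix(0L, n, ncol(e), dimnames = dimnames(e))
  for (i in seq_len(n)) {
    counts[i, ] <- rng(stats::rmultinom(1, depth[i], e[i, ]))[, 1]
  }
  out <- otu_table(counts)
  attr(out, "niche_params") <- params
  out
}

#' Simulate a random rooted coalescent tree over OTU ids
#'
#' @param otu_ids Character vector of unique tip labels (length >= 2).
#' @param seed Integer seed; the same seed yields the identical tree.
#' @return A rooted, bifurcating [ape::phylo] tree with positive branch
#'   lengths.
#' @export
simulate_tree <- function(otu_ids, seed = 1L) {
  if (anyDuplicated(otu_ids)) stop("duplicate OTU ids", call. = FALSE)
  if (length(otu_ids) < 2) stop("need at least 2 ids", call. = FALSE)
  rng <- local_rng(seed)
  rng(ape::rcoal(length(otu_ids), tip.label = otu_ids))
}

#' Run the full synthetic generator
#'
#' @param scenario A [gradient_scenario()].
#' @return A list of class `gradient_simulation` with elements `metadata`,
#'   `table`, `tree`, `scenario`, and `niche_params` (the generating truth).
#' @export
simulate_gradient <- function(scenario = gradient_scenario()) {
  metadata <- simulate_metadata(scenario)
  params <- otu_niche_params(scenario)
  table <- simulate_community(scenario, metadata, params = params)
  tree <- simulate_tree(otu_ids(table), seed = scenario$seed + 3L)
  structure(
    list(
      metadata = metadata, table = table, tree = tree,
      scenario = scenario, niche_params = params
    ),
    class = "gradient_simulation"
  )
}

#' @export
print.gradient_simulation <- function(x, ...) {
  cat(sprintf(
    "<gradient_simulation> %d samples, %d OTUs, seed %d\n",
    nrow(x$table), ncol(x$table), x$scenario$seed
  ))
  invisible(x)
}

#' Generate data from a recursive latent path model
#'
#' Latent scores follow the linear recursive system defined by a directed
#' acyclic path matrix over the latents (by default climate, plant, soil,
#' community, the causal chain climate -> plant -> soil -> community).
#' Residual variances are variance-completing so every latent has unit
#' population variance and the entries of `path_coeffs` are standardized
#' path coefficients. Each latent gets one manifest indicator per loading:
#' `indicator = loading * latent + noise_sd * e`.
#'
#' @param path_coeffs Square numeric matrix, `path_coeffs[to, from]` = path
#'   coefficient from latent `from` to latent `to`; must be acyclic.
#' @param n Number of rows (samples).
#' @param noise_sd Indicator (measurement) noise standard deviation.
#' @param loadings Loadings of the manifest indicators of every latent.
#' @param seed Integer seed.
#' @return A tibble of manifest columns named `<latent>_1`, `<latent>_2`, ...;
#'   the latent scores are attached as attribute `latents`.
#' @export
simulate_sem_data <- function(path_coeffs, n, noise_sd = 0.1,
                              loadings = c(0.9, 0.8), seed = 1L) {
  p <- as.matrix(path_coeffs)
  if (is.null(rownames(p))) {
    rownames(p) <- colnames(p) <- paste0("lv", seq_len(nrow(p)))
  }
  lv <- rownames(p)
  ord <- topological_order(p != 0)
  if (is.null(ord)) stop("path matrix is cyclic", call. = FALSE)
  rng <- local_rng(seed)
  k <- length(lv)
  eta <- matrix(0, n, k, dimnames = list(NULL, lv))
  cpop <- diag(k)
  dimnames(cpop) <- list(lv, lv)
  for (j in ord) {
    preds <- which(p[j, ] != 0)
    if (length(preds) == 0) {
      eta[, j] <- rng(stats::rnorm(n))
      next
    }
    b <- p[j, preds]
    var_lin <- drop(t(b) %*% cpop[preds, preds, drop = FALSE] %*% b)
    if (var_lin >= 1) {
      stop("path coefficients imply non-positive residual variance", call. = FALSE)
    }
    eta[, j] <- eta[, preds, drop = FALSE] %*% b + sqrt(1 - var_lin) * rng(stats::rnorm(n))
    cpop[j, ] <- cpop[, j] <- drop(cpop[, preds, drop = FALSE] %*% b)
    cpop[j, j] <- 1
  }
  out <- list()
  for (j in seq_len(k)) {
    for (m in seq_along(loadings)) {
      out[[paste0(lv[j], "_", m)]] <-
        loadings[m] * eta[, j] + noise_sd * rng(stats::rnorm(n))
    }
  }
  res <- tibble::as_tibble(out)
  attr(res, "latents") <- eta
  res
}

# indices in an order such that every latent comes after its predictors;
# NULL if the graph has a cycle. adj[to, from] = TRUE for an edge from -> to.
topological_order <- function(adj) {
  k <- nrow(adj)
  remaining <- seq_len(k)
  ord <- integer(0)
  while (length(remaining) > 0) {
    indeg <- vapply(remaining, function(j) sum(adj[j, remaining]), numeric(1))
    src <- remaining[indeg == 0]
    if (length(src) == 0) {
      return(NULL)
    }
    ord <- c(ord, src)
    remaining <- setdiff(remaining, src)
  }
  ord
}
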