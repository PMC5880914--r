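#' Required metadata columns
#'
#' Per-sample environmental, spatial, climate and plant attributes used by the
#' pipeline. Units: elevation m; latitude/longitude decimal degrees; TC, TN,
#' DB, EB, DC percent; NH4, NO3 mg per kg dry soil; conductivity uS/cm;
#' T10 and MAT degrees C; MAP mm; PSR species count.
#' @keywords internal
metadata_required_cols <- c(
  "sample_id", "site_id", "elevation", "latitude", "longitude",
  "vegetation_type", "pH", "TC", "TN", "NH4", "NO3", "conductivity",
  "T10", "MAP", "MAT", "PSR", "DB", "EB", "DC"
)

#' Read and validate a sample metadata table
#'
#' Tab-separated, one row per sample. Extra columns beyond the required set
#' are preserved as covariates. Validation enforces pH in (0, 14),
#' percentages in \[0, 100\] and positive elevation.
#'
#' @param path File path to a tab-separated table.
#' @return A tibble with one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(tibble::as_tibble(df))
}

#' @rdname read_metadata
#' @param metadata A data frame of per-sample attributes.
#' @export
validate_metadata <- function(metadata) {
  metadata <- tibble::as_tibble(metadata)
  missing <- setdiff(metadata_required_cols, names(metadata))
  if (length(missing) > 0) {
    stop("missing required metadata column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (any(metadata$pH <= 0 | metadata$pH >= 14)) {
    stop("pH outside (0, 14) for sample(s): ",
      paste(metadata$sample_id[metadata$pH <= 0 | metadata$pH >= 14], collapse = ", "),
      call. = FALSE
    )
  }
  for (col in c("TC", "TN", "DB", "EB", "DC")) {
    v <- metadata[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      stop(sprintf("%s outside [0, 100]", col), call. = FALSE)
    }
  }
  if (any(metadata$elevation <= 0)) stop("elevation must be > 0", call. = FALSE)
  metadata
}

#' Write a metadata table to tab-separated text
#' @param metadata A metadata tibble.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a metadata table to an OTU table by sample id
#'
#' Alignment is always by id, never by position. Errors if the two id sets
#' differ.
#'
#' @param metadata A metadata tibble.
#' @param table An [otu_table()].
#' @return The metadata reordered to match `sample_ids(table)`.
#' @export
align_metadata <- function(metadata, table) {
  ids <- sample_ids(table)
  if (!setequal(metadata$sample_id, ids)) {
    stop("metadata sample ids do not match OTU table sample ids", call. = FALSE)
  }
  metadata[match(ids, metadata$sample_id), , drop = FALSE]
}

#' Split samples into lower and higher elevational sections
#'
#' The study gradient separates into a lower and a higher section; the default
#' threshold of 2700 m is the midpoint of the observed regime change between
#' 2600 and 2800 m.
#'
#' @param metadata A metadata tibble.
#' @param threshold Threshold elevation in metres (lower: elevation <
#'   threshold; higher: elevation >= threshold).
#' @return A list with elements `threshold`, `lower_ids`, `higher_ids`.
#' @export
gradient_sections <- function(metadata, threshold = 2700) {
  lower <- metadata$sample_id[metadata$elevation < threshold]
  higher <- metadata$sample_id[metadata$elevation >= threshold]
  structure(
    list(threshold = threshold, lower_ids = lower, higher_ids = higher),
    class = "gradient_sections"
  )
}

#' @export
print.gradient_sections <- function(x, ...) {
  cat(sprintf(
    "<gradient_sections> threshold %g m: %d lower, %d higher samples\n",
    x$threshold, length(x$lower_ids), length(x$higher_ids)
  ))
  invisible(x)
}

#' Analysis configuration
#'
#' Collects the replication counts and global settings shared by the
#' pipeline stages. Every stochastic result object records the seed it used.
#'
#' @param n_permutations Label permutations for hypothesis tests.
#' @param n_null_iterations Null-model randomisations.
#' @param n_bootstrap Bootstrap resamples for the fraction test.
#' @param rarefaction_depth Reads per sample after rarefaction (no default is
#'   claimed; set explicitly when rarefying).
#' @param random_seed Integer seed.
#' @param alpha Significance level.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(n_permutations = 999, n_null_iterations = 999,
                            n_bootstrap = 999, rarefaction_depth = NULL,
                            random_seed = 1L, alpha = 0.05) {
  stopifnot(
    n_permutations >= 1, n_null_iterations >= 1, n_bootstrap >= 1,
    is.null(rarefaction_depth) || rarefaction_depth >= 1,
    alpha > 0, alpha < 1
  )
  structure(
    list(
      n_permutations = as.integer(n_permutations),
      n_null_iterations = as.integer(n_null_iterations),
      n_bootstrap = as.integer(n_bootstrap),
      rarefaction_depth = rarefaction_depth,
      random_seed = as.integer(random_seed),
      alpha = alpha
    ),
    class = "analysis_config"
  )
}
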