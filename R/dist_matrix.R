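#' Square symmetric distance / deviation matrix container
#'
#' Every beta-level procedure consumes this container. `kind = "dissimilarity"`
#' enforces non-negativity and a zero diagonal; `kind = "deviation"` (used for
#' beta-deviation z-score matrices) allows negative off-diagonal entries.
#'
#' @param values Square numeric matrix.
#' @param ids Optional character ids (defaults to dimnames).
#' @param kind `"dissimilarity"` or `"deviation"`.
#' @return A `dist_matrix`: the matrix with a `kind` attribute.
#' @export
dist_matrix <- function(values, ids = NULL, kind = c("dissimilarity", "deviation")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square", call. = FALSE)
  if (!is.null(ids)) dimnames(values) <- list(ids, ids)
  if (is.null(rownames(values))) {
    ids <- paste0("sample_", seq_len(nrow(values)))
    dimnames(values) <- list(ids, ids)
  }
  if (max(abs(values - t(values))) > 1e-12) {
    stop("matrix is not symmetric (tolerance 1e-12)", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (kind == "dissimilarity") {
    if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
    if (any(values < 0)) stop("dissimilarities must be non-negative", call. = FALSE)
    diag(values) <- 0
  }
  structure(values, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf(
    "<dist_matrix> %d x %d, kind = %s\n", nrow(x), ncol(x),
    attr(x, "kind")
  ))
  invisible(x)
}

dm_kind <- function(x) attr(x, "kind") %||% "dissimilarity"

#' Lower-triangle vector of a square matrix
#' @param x Square matrix.
#' @return Numeric vector of the strictly-lower-triangular entries.
#' @export
lower_tri <- function(x) x[lower.tri(x)]

#' Read / write a square tab-separated distance matrix
#'
#' On-disk layout: ids as header and first column.
#' @param path File path.
#' @param kind Matrix kind, see [dist_matrix()].
#' @export
read_dist_matrix <- function(path, kind = c("dissimilarity", "deviation")) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  dist_matrix(m, kind = match.arg(kind))
}

#' @rdname read_dist_matrix
#' @param x A `dist_matrix`.
#' @export
write_dist_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Great-circle distances among samples, in kilometres
#'
#' Haversine distances on a sphere of radius 6371 km from the metadata's
#' longitude/latitude columns.
#'
#' @param metadata Metadata tibble with `sample_id`, `longitude`, `latitude`.
#' @return A `dist_matrix` of kind dissimilarity, in km.
#' @export
geo_distance_km <- function(metadata) {
  pts <- cbind(metadata$longitude, metadata$latitude)
  m <- geosphere::distm(pts, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371000)
  }) / 1000
  dist_matrix(m, ids = metadata$sample_id)
}

#' Convert a deviation matrix to a dissimilarity for constrained ordination
#'
#' Beta-deviation z-score matrices can be negative; before entering dbRDA they
#' are reflected about their maximum: d'_ij = max(z) - z_ij (larger deviation
#' similarity becomes smaller distance), with a zero diagonal.
#'
#' @param x A `dist_matrix` of kind deviation.
#' @return A `dist_matrix` of kind dissimilarity; the shift applied is stored
#'   in attribute `shift`.
#' @export
deviation_to_dissimilarity <- function(x) {
  if (dm_kind(x) != "deviation") {
    return(x)
  }
  m <- unclass(x)
  off <- m[row(m) != col(m)]
  zmax <- max(off)
  d <- zmax - m
  diag(d) <- 0
  out <- dist_matrix(d, kind = "dissimilarity")
  attr(out, "shift") <- zmax
  out
}

subset_dist <- function(x, ids) {
  dist_matrix(unclass(x)[ids, ids, drop = FALSE], kind = dm_kind(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
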