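#' Construct an OTU count table
#'
#' The community observation unit: a samples x OTUs matrix of non-negative
#' integer read counts with unique sample and OTU identifiers, optionally
#' carrying a per-OTU taxonomy string.
#'
#' @param counts Numeric matrix, samples in rows and OTUs in columns. All
#'   entries must be non-negative and integral. Row names are sample ids,
#'   column names are OTU ids (or supply `sample_ids` / `otu_ids`).
#' @param sample_ids,otu_ids Optional character vectors overriding dimnames.
#' @param taxonomy Optional character vector of lineage strings, one per OTU.
#' @return An object of class `otu_table`: the validated integer matrix with
#'   a `taxonomy` attribute.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("s1", "s2"), c("o1", "o2")))
#' tab <- otu_table(m)
#' total_counts(tab)
#' @export
otu_table <- function(counts, sample_ids = NULL, otu_ids = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(otu_ids)) colnames(counts) <- otu_ids
  if (is.null(rownames(counts)) && nrow(counts) > 0) {
    rownames(counts) <- paste0("sample_", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts)) && ncol(counts) > 0) {
    colnames(counts) <- paste0("otu_", seq_len(ncol(counts)))
  }
  validate_counts(counts)
  storage.mode(counts) <- "integer"
  structure(counts, taxonomy = taxonomy, class = c("otu_table", "matrix", "array"))
}

validate_counts <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric count at OTU '%s', sample '%s'",
      colnames(counts)[bad[2]], rownames(counts)[bad[1]]
    ), call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "negative count at OTU '%s', sample '%s'",
      colnames(counts)[bad[2]], rownames(counts)[bad[1]]
    ), call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-integral count at OTU '%s', sample '%s'",
      colnames(counts)[bad[2]], rownames(counts)[bad[1]]
    ), call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate OTU ids", call. = FALSE)
  invisible(counts)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf(
    "<otu_table> %d samples x %d OTUs, %s reads total\n",
    nrow(x), ncol(x), format(sum(x), big.mark = ",")
  ))
  invisible(x)
}

#' @rdname otu_table
#' @param x An `otu_table`.
#' @export
sample_ids <- function(x) rownames(x)

#' @rdname otu_table
#' @export
otu_ids <- function(x) colnames(x)

#' @rdname otu_table
#' @export
total_counts <- function(x) rowSums(unclass(x))

#' Read an OTU table from disk
#'
#' Tab-separated tables follow the common amplicon convention of OTUs in rows
#' and samples in columns (first column OTU ids, header sample ids); they are
#' transposed to the internal samples x OTUs orientation. BIOM-style JSON
#' (BIOM 1.0) is read through the biomformat package.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(raw[[1]])
    m <- as.matrix(raw[, -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    rownames(m) <- ids
    otu_table(t(m))
  } else {
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b)) # OTUs x samples
    otu_table(t(m))
  }
}

#' Write an OTU table
#'
#' @param x An [otu_table()].
#' @param path Output file path.
#' @param format `"tsv"` (OTUs x samples on disk) or `"biom-json"`.
#' @export
write_otu_table <- function(x, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    m <- t(unclass(x))
    df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  } else {
    b <- biomformat::make_biom(t(unclass(x)))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}
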