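#' Read a rooted phylogenetic tree from a newick file
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the pipeline
#' relies on: unique leaf labels, non-negative branch lengths, and a rooted
#' topology. Missing branch lengths are set to 0 with a warning.
#'
#' @param path Path to a newick file (or a newick string via `text`).
#' @param text Optional newick string instead of a file.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("newick parse error (unbalanced parentheses or malformed input)",
      call. = FALSE
    )
  }
  validate_tree(tr)
}

#' @rdname read_tree
#' @param tree An [ape::phylo] object.
#' @export
validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels", call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths; defaulting to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree)) {
    warning("tree is unrooted; rooting at the first internal node")
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  tree
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
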