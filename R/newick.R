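#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that strips square-bracket comments,
#' tolerates quoted labels, checks parenthesis balance, and fills in missing
#' branch lengths with 0 (with a warning).
#'
#' @param path Path to a Newick file (first tree is used).
#' @param text Newick string, as an alternative to `path`.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  text <- gsub("\\[[^]]*\\]", "", text) # comments
  no_quote <- gsub("'[^']*'", "", text)
  n_open <- lengths(regmatches(no_quote, gregexpr("\\(", no_quote)))
  n_close <- lengths(regmatches(no_quote, gregexpr("\\)", no_quote)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick input (", n_open, " '(' vs ",
         n_close, "')')")
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  tr$tip.label <- gsub("^'(.*)'$", "\\1", tr$tip.label)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  tr
}

#' Write a tree to Newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
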