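#' Reads per kilobase per million mapped reads
#'
#' `rpkm = counts * 1e9 / (gene_length_bp * library_size)`.
#'
#' @param counts Numeric vector/matrix of mapped-read counts (genes x
#'   tissues).
#' @param gene_length_bp Gene (transcript) length in bp, recycled over rows.
#' @param library_size Total mapped reads per tissue, recycled over columns.
#' @return RPKM values with the shape of `counts`.
#' @export
rpkm <- function(counts, gene_length_bp, library_size) {
  if (any(gene_length_bp <= 0)) stop("gene lengths must be positive")
  if (any(library_size <= 0)) stop("library sizes must be positive")
  if (any(counts < 0)) stop("negative read counts")
  if (is.matrix(counts)) {
    sweep(sweep(counts * 1e9, 1, gene_length_bp, `/`), 2, library_size,
          `/`)
  } else {
    counts * 1e9 / (gene_length_bp * library_size)
  }
}

#' Read an expression table
#'
#' Long-format TSV with columns `gene`, `tissue`, `reads`, `gene_length`,
#' `library_size` ('#'-prefixed comment lines allowed).
#'
#' @param path TSV path.
#' @return Data frame with those columns.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene", "tissue", "reads", "gene_length", "library_size")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("expression table lacks columns: ",
         paste(missing, collapse = ", "))
  }
  df
}

# per-tissue RPKM profile (named vector) from a long expression table
rpkm_profile <- function(tab) {
  v <- rpkm(tab$reads, tab$gene_length, tab$library_size)
  stats::setNames(v, tab$tissue)
}

#' Pearson correlation with a two-sided p value
#'
#' @param x,y Numeric vectors, length >= 3, both with positive variance.
#' @return List with `r` and `p` (two-sided, t reference with n - 2 df).
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Four-way expression correlation panel for a paralog pair
#'
#' On RPKM profiles restricted to the tissues shared by all three genes
#' (minus any excluded tissues), computes the four Pearson correlations:
#' copy a vs outgroup, copy b vs outgroup, the per-tissue mean of the two
#' copies vs outgroup, and copy a vs copy b.
#'
#' @param copy_a,copy_b,outgroup Long expression tables (see
#'   [read_expression_table()]) each describing one gene over tissues.
#' @param exclude_tissues Tissues to drop before correlating (e.g.
#'   `"testis"`).
#' @return Data frame with rows `a_vs_outgroup`, `b_vs_outgroup`,
#'   `avg_vs_outgroup`, `a_vs_b`: columns `comparison`, `r`, `p`,
#'   `significance` (`""`, `"*"` p < 0.05, `"**"` p < 0.01); attribute
#'   `tissues_used`.
#' @export
correlation_panel <- function(copy_a, copy_b, outgroup,
                              exclude_tissues = character(0)) {
  pa <- rpkm_profile(copy_a)
  pb <- rpkm_profile(copy_b)
  po <- rpkm_profile(outgroup)
  shared <- Reduce(intersect, list(names(pa), names(pb), names(po)))
  if (length(shared) <
      max(length(pa), length(pb), length(po))) {
    warning("tissue sets differ; using the ", length(shared),
            " shared tissues")
  }
  shared <- setdiff(shared, exclude_tissues)
  if (length(shared) < 3L) {
    stop("fewer than 3 shared tissues after exclusion")
  }
  pa <- pa[shared]; pb <- pb[shared]; po <- po[shared]
  comps <- list(
    a_vs_outgroup = list(pa, po),
    b_vs_outgroup = list(pb, po),
    avg_vs_outgroup = list((pa + pb) / 2, po),
    a_vs_b = list(pa, pb)
  )
  out <- do.call(rbind, lapply(names(comps), function(nm) {
    res <- pearson_with_p(comps[[nm]][[1]], comps[[nm]][[2]])
    data.frame(comparison = nm, r = res$r, p = res$p,
               significance = if (res$p < 0.01) "**"
                              else if (res$p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  }))
  attr(out, "tissues_used") <- shared
  out
}
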