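#' Protein alignment container
#'
#' A protein alignment is a data frame of equal-length gapped rows. The
#' constructor validates rectangularity and id uniqueness.
#'
#' @param records Data frame with `id` and `residues` columns (as returned by
#'   [read_fasta()]), all rows the same length.
#' @return The records with class `protein_alignment` and attribute
#'   `n_columns`.
#' @export
protein_alignment <- function(records) {
  stopifnot(NROW(records) >= 1L)
  lens <- nchar(records$residues)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows differ in length: ",
         paste(range(lens), collapse = " vs "))
  }
  if (lens[1] < 1L) stop("alignment has zero columns")
  if (anyDuplicated(records$id)) stop("duplicate row ids")
  structure(records, class = c("protein_alignment", "data.frame"),
            n_columns = lens[1])
}

#' Codon alignment container
#'
#' In-frame aligned coding sequences: every row is `3 * n_codons` long, gap
#' codons are exactly `---`, and no ungapped codon is a stop codon.
#'
#' @param records Data frame with `id` and `residues` (nucleotide) columns.
#' @param code A [genetic_code()].
#' @return The records with class `codon_alignment` and attributes
#'   `n_codons` and `code_id`.
#' @export
codon_alignment <- function(records, code = genetic_code()) {
  stopifnot(NROW(records) >= 1L)
  lens <- nchar(records$residues)
  if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
  if (lens[1] %% 3L != 0L) stop("row length not divisible by 3")
  if (anyDuplicated(records$id)) stop("duplicate row ids")
  for (i in seq_len(NROW(records))) {
    row <- toupper(records$residues[i])
    cods <- codon_split(row)
    bad <- grepl("-", cods) & cods != "---"
    if (any(bad)) {
      stop("row '", records$id[i], "': partial gap codon at codon ",
           which(bad)[1])
    }
    stops <- cods %in% code$stop_codons
    if (any(stops)) {
      stop("row '", records$id[i], "': stop codon at codon ",
           which(stops)[1])
    }
  }
  structure(records, class = c("codon_alignment", "data.frame"),
            n_codons = lens[1] %/% 3L, code_id = code$code_id)
}

codon_split <- function(row) {
  n <- nchar(row)
  substring(row, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon alignment:", NROW(x), "rows x", attr(x, "n_codons"),
      "codons\n")
  invisible(x)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein alignment:", NROW(x), "rows x", attr(x, "n_columns"),
      "columns\n")
  invisible(x)
}

# alignment rows as a character matrix (rows x columns), 1 char per cell
alignment_matrix <- function(records) {
  do.call(rbind, strsplit(records$residues, ""))
}
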