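#' Genetic code table
#'
#' Builds a genetic-code object: the 64-codon to amino-acid map and the set of
#' sense (non-stop) codons that index the states of the codon substitution
#' models. Only the standard nuclear code is bundled; nuclear CDS of the
#' vertebrates considered here all use it.
#'
#' @param code_id Identifier of the code; currently only `"standard"`.
#' @return An object of class `genetic_code` with elements `code_id`,
#'   `codons` (all 64), `aa` (named amino-acid map, `*` = stop),
#'   `sense_codons` (61 for the standard code) and `stop_codons`.
#' @examples
#' gc <- genetic_code()
#' length(gc$sense_codons) # 61
#' @export
genetic_code <- function(code_id = "standard") {
  if (!identical(code_id, "standard")) {
    stop("unknown genetic code: ", code_id)
  }
  aa_by_codon <- STANDARD_CODE
  codons <- names(aa_by_codon)
  sense <- codons[aa_by_codon != "*"]
  structure(
    list(
      code_id = code_id,
      codons = codons,
      aa = aa_by_codon,
      sense_codons = sense,
      stop_codons = setdiff(codons, sense)
    ),
    class = "genetic_code"
  )
}

# standard nuclear code (Biostrings table, TCAG order within each position)
STANDARD_CODE <- Biostrings::GENETIC_CODE

# IUPAC nucleotide ambiguity sets (used to expand tip states)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Translate a codon sequence
#'
#' Translates an in-frame nucleotide string to amino acids. Gap codons
#' (`---`) become `-`; a codon containing ambiguity codes translates to `X`
#' unless all compatible codons agree; internal stop codons are an error.
#'
#' @param codon_row Nucleotide string, length divisible by 3.
#' @param code A [genetic_code()].
#' @return Amino-acid string of length `nchar(codon_row) / 3`.
#' @examples
#' translate_codons("ATG---TGG") # "M-W"
#' @export
translate_codons <- function(codon_row, code = genetic_code()) {
  n <- nchar(codon_row)
  if (n %% 3L != 0L) {
    stop("sequence length ", n, " is not a multiple of 3")
  }
  cods <- substring(toupper(codon_row), seq(1L, n, 3L), seq(3L, n, 3L))
  out <- character(length(cods))
  for (i in seq_along(cods)) {
    cd <- cods[i]
    if (cd == "---") {
      out[i] <- "-"
    } else if (cd %in% names(STANDARD_CODE)) {
      aa <- STANDARD_CODE[[cd]]
      if (aa == "*") {
        stop("stop codon '", cd, "' at codon position ", i)
      }
      out[i] <- aa
    } else {
      comp <- expand_ambiguous_codon(cd)
      aas <- unique(STANDARD_CODE[comp])
      out[i] <- if (length(aas) == 1L && aas != "*") aas else "X"
    }
  }
  paste(out, collapse = "")
}

# all unambiguous codons compatible with an IUPAC/gapped codon; a codon with
# any gap character mixed with bases is treated as fully missing
expand_ambiguous_codon <- function(cd) {
  chars <- strsplit(cd, "")[[1]]
  sets <- lapply(chars, function(ch) {
    if (ch == "-") c("A", "C", "G", "T") else IUPAC_SETS[[ch]]
  })
  if (any(vapply(sets, is.null, logical(1)))) {
    stop("unrecognized nucleotide in codon '", cd, "'")
  }
  grid <- expand.grid(sets[[1]], sets[[2]], sets[[3]],
                      stringsAsFactors = FALSE)
  paste0(grid[[1]], grid[[2]], grid[[3]])
}
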