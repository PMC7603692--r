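#' Read a FASTA file
#'
#' Parses protein or nucleotide FASTA (gaps allowed) into a data frame of
#' sequence records. The id is the first whitespace-delimited token of the
#' header; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `id`, `description`, `residues`, in
#'   file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(ids))) stop("empty sequence id in ", path)
  data.frame(
    id = ids, description = desc,
    residues = as.character(set),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` recovers `x`.
#' Gap characters are written verbatim.
#'
#' @param records Data frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (NROW(records) == 0L) stop("no records to write")
  desc <- if ("description" %in% names(records)) records$description else ""
  headers <- ifelse(nzchar(desc),
                    paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
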