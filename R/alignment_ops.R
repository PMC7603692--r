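#' Mean ungapped sequence length
#'
#' @param records Data frame with a `residues` column (gapped or not).
#' @return Arithmetic mean of gap-free residue counts.
#' @export
average_ungapped_length <- function(records) {
  stopifnot(NROW(records) >= 1L)
  mean(ungapped_lengths(records))
}

ungapped_lengths <- function(records) {
  nchar(gsub("-", "", records$residues, fixed = TRUE))
}

#' Exclude sequences much shorter than the average
#'
#' Two-pass rule: compute the mean ungapped length, drop sequences shorter
#' than `fraction` of it, then recompute the mean on the survivors (the
#' final average used downstream for trimming).
#'
#' @param records Sequence records.
#' @param fraction Exclusion threshold as a fraction of the mean
#'   (default 0.6).
#' @return List with `kept`, `excluded` (both record data frames) and
#'   `final_average` (mean ungapped length of the kept records).
#' @export
filter_short_sequences <- function(records, fraction = 0.6) {
  stopifnot(NROW(records) >= 1L, fraction > 0, fraction < 1)
  lens <- ungapped_lengths(records)
  cutoff <- fraction * mean(lens)
  keep <- lens >= cutoff
  if (!any(keep)) stop("all sequences shorter than the cutoff")
  list(
    kept = records[keep, , drop = FALSE],
    excluded = records[!keep, , drop = FALSE],
    final_average = mean(lens[keep])
  )
}

#' Per-column gap and residue profile of an alignment
#'
#' @param alignment A [protein_alignment()] (or any rectangular records).
#' @return Data frame with `column` (1-based) and `gap_fraction`.
#' @export
column_profile <- function(alignment) {
  m <- alignment_matrix(alignment)
  data.frame(
    column = seq_len(ncol(m)),
    gap_fraction = colMeans(m == "-")
  )
}

#' Trim an alignment to a target length by removing gappy columns
#'
#' Removes columns in decreasing order of gap fraction until
#' `ceiling(target_length)` columns remain. Among columns with equal gap
#' fraction the rightmost is removed first; a gap-free column is never
#' removed before a gappier one.
#'
#' @param alignment A [protein_alignment()].
#' @param target_length Target column count (e.g. the average ungapped
#'   sequence length); non-integers are rounded up.
#' @return The trimmed [protein_alignment()], row order preserved, with
#'   attribute `kept_columns` giving the original indices of the surviving
#'   columns.
#' @export
trim_to_average <- function(alignment, target_length) {
  if (target_length <= 0) stop("target_length must be positive")
  ncols <- attr(alignment, "n_columns")
  target <- as.integer(ceiling(target_length))
  if (target > ncols) stop("target_length exceeds alignment width")
  if (target == ncols) {
    out <- alignment
    attr(out, "kept_columns") <- seq_len(ncols)
    return(out)
  }
  m <- alignment_matrix(alignment)
  gf <- colMeans(m == "-")
  # order of removal: gappiest first, rightmost first on ties
  removal <- order(gf, seq_along(gf), decreasing = TRUE)
  drop <- removal[seq_len(ncols - target)]
  keep <- sort(setdiff(seq_len(ncols), drop))
  res <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- alignment
  out$residues <- unname(res)
  out <- protein_alignment(out)
  attr(out, "kept_columns") <- keep
  out
}

#' Consensus sequence of an alignment
#'
#' Per column the most frequent symbol is taken; if that symbol is the gap,
#' the most frequent non-gap residue is taken instead, so the consensus
#' never contains gaps. Residue ties break alphabetically.
#'
#' @param alignment A [protein_alignment()].
#' @return List with `residues` (consensus string, no gaps) and
#'   `source_column` (1-based column of origin for each position).
#' @export
consensus <- function(alignment) {
  m <- alignment_matrix(alignment)
  out <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    tab <- tab[order(-tab, names(tab))] # ties alphabetical
    top <- names(tab)[1]
    if (top == "-") {
      tab <- tab[names(tab) != "-"]
      if (length(tab) == 0L) {
        stop("column ", j, " is entirely gaps; no consensus residue")
      }
      top <- names(tab)[1]
    }
    out[j] <- top
  }
  list(residues = paste(out, collapse = ""),
       source_column = seq_len(ncol(m)))
}

#' Back-translate a trimmed protein alignment to codons
#'
#' Each aligned amino acid is replaced by its source codon from the
#' (unaligned, in-frame) CDS; gaps become `---`. The CDS translation must
#' contain the row's ungapped residues in order; trimming is handled by
#' aligning each protein row to its full translation and skipping the
#' trimmed-out leading/internal residues is NOT attempted - rows must be
#' back-translatable column by column, which holds when the CDS is the
#' coding sequence of the (untrimmed) protein and trimmed columns removed
#' whole residues from every row alike.
#'
#' @param alignment A [protein_alignment()] (possibly trimmed, see Details).
#' @param cds_records Data frame of CDS records with ids matching the
#'   alignment rows.
#' @param code A [genetic_code()].
#' @param kept_columns Optional integer vector: for a trimmed alignment, the
#'   original column indices retained (attribute `kept_columns` of
#'   [trim_to_average()]); requires `full_alignment` to locate source
#'   residues.
#' @param full_alignment The untrimmed alignment, required with
#'   `kept_columns`.
#' @return A [codon_alignment()] with `translate_codons()` of every row equal
#'   to the protein row.
#' @export
back_translate <- function(alignment, cds_records, code = genetic_code(),
                           kept_columns = NULL, full_alignment = NULL) {
  cds_idx <- match(alignment$id, cds_records$id)
  if (anyNA(cds_idx)) {
    stop("no CDS for row(s): ",
         paste(alignment$id[is.na(cds_idx)], collapse = ", "))
  }
  rows <- alignment$residues
  src_rows <- if (!is.null(kept_columns)) {
    stopifnot(!is.null(full_alignment))
    full_alignment$residues[match(alignment$id, full_alignment$id)]
  } else {
    rows
  }
  out <- character(length(rows))
  for (i in seq_along(rows)) {
    cds <- toupper(gsub("-", "", cds_records$residues[cds_idx[i]],
                        fixed = TRUE))
    cods <- codon_split(cds)
    prot_full <- strsplit(toupper(src_rows[i]), "")[[1]]
    # codon index for each column of the full row (NA at gaps)
    codon_of_col <- ifelse(prot_full == "-", NA_integer_,
                           cumsum(prot_full != "-"))
    if (max(codon_of_col, 0, na.rm = TRUE) > length(cods)) {
      stop("row '", alignment$id[i], "': CDS shorter than protein row")
    }
    # verify residues match the CDS translation
    ungapped_cols <- which(!is.na(codon_of_col))
    for (k in ungapped_cols) {
      cd <- cods[codon_of_col[k]]
      aa <- translate_codons(cd, code)
      if (aa != "X" && aa != prot_full[k]) {
        stop("row '", alignment$id[i], "': CDS/protein mismatch at ",
             "alignment column ", k, " (codon ", cd, " -> ", aa,
             ", protein has ", prot_full[k], ")")
      }
    }
    cols <- if (!is.null(kept_columns)) kept_columns else
      seq_along(prot_full)
    out[i] <- paste(ifelse(is.na(codon_of_col[cols]), "---",
                           cods[codon_of_col[cols]]),
                    collapse = "")
  }
  codon_alignment(data.frame(id = alignment$id, description = "",
                             residues = out, stringsAsFactors = FALSE),
                  code = code)
}

#' Map selected sites onto conserved-domain intervals
#'
#' Assigns each site (1-based consensus coordinate) to the domain interval
#' containing it, or to the inter-domain region preceding the next domain.
#' Method provenance tags (e.g. E/F/M) are preserved and merged per site.
#'
#' @param site_positions Data frame with `site` (integer) and `method`
#'   (single-letter tag) columns; a site found by several methods appears on
#'   several rows.
#' @param domain_annotation Data frame with `name`, `start`, `end`
#'   (1-based, closed, non-overlapping, sorted or not).
#' @param consensus_length Total length of the consensus coordinate system.
#' @return Data frame with one row per distinct site: `site`, `methods`
#'   (tags collapsed, e.g. "EF"), `region` (domain name or
#'   `"before <domain>"` / `"after <last domain>"`), `in_domain` (logical).
#' @export
map_sites_to_domains <- function(site_positions, domain_annotation,
                                 consensus_length) {
  dom <- domain_annotation[order(domain_annotation$start), , drop = FALSE]
  if (nrow(dom) > 1L && any(dom$start[-1] <= dom$end[-nrow(dom)])) {
    stop("overlapping domain intervals")
  }
  if (any(dom$start > dom$end)) stop("domain start > end")
  sites <- sort(unique(site_positions$site))
  if (any(sites < 1L | sites > consensus_length)) {
    stop("site position outside consensus coordinates (1..",
         consensus_length, ")")
  }
  methods <- vapply(sites, function(s) {
    tags <- sort(unique(site_positions$method[site_positions$site == s]))
    paste(tags, collapse = "")
  }, character(1))
  region <- character(length(sites))
  in_domain <- logical(length(sites))
  for (i in seq_along(sites)) {
    s <- sites[i]
    hit <- which(dom$start <= s & s <= dom$end)
    if (length(hit) == 1L) {
      region[i] <- dom$name[hit]
      in_domain[i] <- TRUE
    } else {
      nxt <- which(dom$start > s)
      region[i] <- if (length(nxt) > 0L) {
        paste0("before ", dom$name[nxt[1]])
      } else {
        paste0("after ", dom$name[nrow(dom)])
      }
    }
  }
  data.frame(site = sites, methods = methods, region = region,
             in_domain = in_domain, stringsAsFactors = FALSE)
}
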