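#' Filter blast-style hits by description keyword and organism
#'
#' Retains hits whose description contains the keyword (case-insensitive by
#' default, fixed substring) and whose source organism is on the allow-list;
#' relative order is preserved. This reproduces the first curation step used
#' to pull p300 homologs out of a blastp result table.
#'
#' @param hits Data frame with columns `rank`, `hit_accession`,
#'   `description`, `organism`, `bitscore`, `evalue`.
#' @param keyword Non-empty keyword, e.g. `"p300"`.
#' @param allowed_organisms Character vector of organisms to keep.
#' @param ignore_case Case-insensitive matching (default TRUE).
#' @return The retained rows of `hits`, original order.
#' @export
filter_hits <- function(hits, keyword, allowed_organisms,
                        ignore_case = TRUE) {
  if (!nzchar(keyword)) stop("keyword must be non-empty")
  if (length(allowed_organisms) == 0L) {
    stop("allowed_organisms is empty: this would drop every hit")
  }
  keep <- grepl(keyword, hits$description,
                fixed = !ignore_case, ignore.case = ignore_case) &
    hits$organism %in% allowed_organisms
  hits[keep, , drop = FALSE]
}

#' Select one sequence per gene from filtered hits
#'
#' Applies the per-gene selection rule: among the hits resolving to a gene
#' id, pick the lowest-rank hit carrying status `VALIDATED` if any does,
#' otherwise the lowest-rank hit overall. Rank ties are broken by accession
#' order for determinism.
#'
#' @param hits Filtered hit table (see [filter_hits()]).
#' @param gene_records Data frame with `gene_id`, `species`, `status`,
#'   `protein_accession` (an extract of NCBI gene2accession).
#' @return Data frame with one row per gene id present in `hits`:
#'   `gene_id`, `species`, `protein_accession`, `status`, `rank`.
#' @export
select_per_gene <- function(hits, gene_records) {
  gr <- gene_records
  gr$status <- toupper(trimws(gr$status))
  idx <- match(hits$hit_accession, gr$protein_accession)
  if (anyNA(idx)) {
    stop("accessions not resolvable to a gene id: ",
         paste(unique(hits$hit_accession[is.na(idx)]), collapse = ", "))
  }
  tab <- data.frame(
    gene_id = gr$gene_id[idx],
    species = gr$species[idx],
    status = gr$status[idx],
    protein_accession = hits$hit_accession,
    rank = hits$rank,
    stringsAsFactors = FALSE
  )
  pick <- lapply(split(tab, tab$gene_id), function(g) {
    g <- g[order(g$rank, g$protein_accession), , drop = FALSE]
    val <- g[g$status == "VALIDATED", , drop = FALSE]
    if (nrow(val) >= 1L) val[1, , drop = FALSE] else g[1, , drop = FALSE]
  })
  out <- do.call(rbind, pick)
  rownames(out) <- NULL
  out[order(out$gene_id), c("gene_id", "species", "protein_accession",
                            "status", "rank")]
}

#' Summarize gene copy numbers per species and group
#'
#' Counts selected genes per species and averages within lineage groups
#' (e.g. fishes vs mammals vs sauropsids). The display mean is rounded to
#' one decimal; the exact mean is retained.
#'
#' @param selection Output of [select_per_gene()], or any data frame with a
#'   `species` column listing one row per selected gene.
#' @param species_groups Data frame with `species` and `group` columns
#'   covering every species in `selection`; species listed here but absent
#'   from the selection count as zero copies.
#' @return List with `per_species` (species, group, copies) and `per_group`
#'   (group, n_species, n_genes, mean_copies, mean_copies_display).
#' @export
copy_number_summary <- function(selection, species_groups) {
  missing_sp <- setdiff(selection$species, species_groups$species)
  if (length(missing_sp) > 0L) {
    stop("species not present in grouping: ",
         paste(missing_sp, collapse = ", "))
  }
  counts <- table(factor(selection$species,
                         levels = species_groups$species))
  per_species <- data.frame(
    species = species_groups$species,
    group = species_groups$group,
    copies = as.integer(counts),
    stringsAsFactors = FALSE
  )
  agg_n <- tapply(per_species$copies, per_species$group, sum)
  agg_s <- tapply(per_species$copies, per_species$group, length)
  grp <- sort(unique(per_species$group))
  per_group <- data.frame(
    group = grp,
    n_species = as.integer(agg_s[grp]),
    n_genes = as.integer(agg_n[grp]),
    mean_copies = as.numeric(agg_n[grp]) / as.numeric(agg_s[grp]),
    stringsAsFactors = FALSE
  )
  per_group$mean_copies_display <- round(per_group$mean_copies, 1)
  list(per_species = per_species, per_group = per_group)
}
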