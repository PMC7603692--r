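#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test. The two-sided p value sums the probabilities
#' of all tables with the observed margins whose probability does not
#' exceed the observed table's (with a 1e-12 slack for ties).
#'
#' @param table 2x2 matrix or a length-4 vector `c(a, b, c, d)` read
#'   row-wise: row 1 = selected/not for group 1, row 2 for group 2.
#' @param sided `"two"` (default), `"greater"` or `"less"` (on the \[1,1\]
#'   cell).
#' @return The p value.
#' @export
fisher_exact_2x2 <- function(table, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  x <- as.vector(t(table))
  if (length(x) != 4L) stop("need a 2x2 table")
  if (any(x < 0) || any(x != round(x))) {
    stop("table entries must be non-negative integers")
  }
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  m <- a + b   # row 1 margin
  n <- c_ + d  # row 2 margin
  k <- a + c_  # column 1 margin
  if (m + n == 0) stop("empty table")
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- switch(sided,
    two = sum(probs[probs <= p_obs * (1 + 1e-12)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a])
  )
  min(p, 1)
}

#' Holm step-down multiple-testing correction
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values (monotone, capped at 1), same order.
#' @export
holm_correction <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Clade-pair model comparison report
#'
#' For each pair of clades, labels the tree (`#1`/`#2` for clade model C;
#' `Test`/`Reference` for the selection-intensity test), runs
#' [fit_clade_model_c()] and [fit_relax()], and assembles a report row per
#' clade mirroring the usual CmC/RELAX result table: shared omega0/omega1
#' with proportions, per-partition omega2, the CmC-vs-M2a_rel p, mean omega
#' per partition, k and the RELAX p.
#'
#' @param alignment A [codon_alignment()].
#' @param tree Unlabeled [ape::phylo] tree.
#' @param clade_pairs List of pairs; each element is a list with `name`,
#'   `clade1` (leaf labels) and `clade2`.
#' @param code A [genetic_code()].
#' @return Data frame with two rows per pair (one per clade): `pair`,
#'   `clade`, `cmc_label`, `omega0`, `p0`, `omega1`, `p1`, `omega2`, `p2`,
#'   `cmc_p`, `relax_label`, `mean_omega`, `k`, `relax_p`.
#' @export
run_clade_comparison <- function(alignment, tree, clade_pairs,
                                 code = genetic_code()) {
  baseline <- fit_m0(alignment, tree, code = code)
  rows <- list()
  for (cp in clade_pairs) {
    t_cmc <- label_clades(tree, list("#1" = cp$clade1, "#2" = cp$clade2))
    bl <- baseline
    bl$td$edge_label <- branch_labels(
      ape::reorder.phylo(t_cmc, "postorder"))
    cmc <- fit_clade_model_c(alignment, t_cmc, baseline = bl, code = code)
    t_rlx <- label_clades(tree, list(Test = cp$clade1,
                                     Reference = cp$clade2))
    bl$td$edge_label <- branch_labels(
      ape::reorder.phylo(t_rlx, "postorder"))
    rlx <- fit_relax(alignment, t_rlx, baseline = bl, code = code)
    m <- cmc$fit$mle
    for (i in 1:2) {
      lab <- c("#1", "#2")[i]
      rlab <- c("Test", "Reference")[i]
      rows[[length(rows) + 1L]] <- data.frame(
        pair = cp$name,
        clade = c(cp$name1 %||% "clade1", cp$name2 %||% "clade2")[i],
        cmc_label = lab,
        omega0 = m$omega0, p0 = m$p0,
        omega1 = 1, p1 = m$p1,
        omega2 = unname(m$omega2[lab]), p2 = m$p2,
        cmc_p = cmc$lrt$p,
        relax_label = rlab,
        mean_omega = unname(rlx$mean_omega[rlab]),
        k = rlx$fit$mle$k,
        relax_p = rlx$lrt$p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a domain-grouped report of positively selected sites
#'
#' Takes per-method site tables (tags E/F/M), merges sites found by several
#' methods into combined superscripts, maps them onto the conserved-domain
#' annotation, and emits the familiar alternating
#' `(sites...)Domain(sites...)` text plus a tidy data frame.
#'
#' @param posterior_tables List of site tables; each needs columns `site`,
#'   `method`, `flagged` (only flagged rows are reported).
#' @param domain_annotation Data frame `name`, `start`, `end` (1-based,
#'   closed, non-overlapping).
#' @param consensus_length Length of the consensus coordinate system.
#' @return List with `sites` (data frame from [map_sites_to_domains()]),
#'   and `text` (single line, domains in order, inter-domain groups in
#'   parentheses, method tags as `^` suffixes).
#' @export
build_site_report <- function(posterior_tables, domain_annotation,
                              consensus_length) {
  flagged <- do.call(rbind, lapply(posterior_tables, function(tb) {
    tb <- tb[tb$flagged, c("site", "method"), drop = FALSE]
    tb
  }))
  if (NROW(flagged) == 0L) {
    flagged <- data.frame(site = integer(0), method = character(0))
  }
  mapped <- map_sites_to_domains(flagged, domain_annotation,
                                 consensus_length)
  dom <- domain_annotation[order(domain_annotation$start), , drop = FALSE]
  fmt_sites <- function(df) {
    if (NROW(df) == 0L) return("")
    paste(paste0(df$site, "^", df$methods), collapse = ", ")
  }
  pieces <- character(0)
  for (i in seq_len(nrow(dom))) {
    before <- mapped[mapped$region == paste0("before ", dom$name[i]), ,
                     drop = FALSE]
    inside <- mapped[mapped$region == dom$name[i], , drop = FALSE]
    pieces <- c(pieces, paste0("(", fmt_sites(before), ")"),
                paste0("(", fmt_sites(inside), ")", dom$name[i]))
  }
  after <- mapped[mapped$region == paste0("after ",
                                          dom$name[nrow(dom)]), ,
                  drop = FALSE]
  pieces <- c(pieces, paste0("(", fmt_sites(after), ")"))
  list(sites = mapped, text = paste(pieces, collapse = ", "))
}

#' Contrast proportions of positively selected branches between groups
#'
#' Counts branches with uncorrected p < 0.05 in each group's branch sweep
#' and compares every pair of groups with Fisher's exact test.
#'
#' @param sweep_results_by_group Named list of branch-sweep data frames
#'   (see [branch_sweep_episodic()]), or of lists `list(selected, total)`.
#' @param alpha Per-branch significance level (default 0.05).
#' @return List with `proportions` (group, selected, total, proportion) and
#'   `contrasts` (group1, group2, p).
#' @export
branch_proportion_contrast <- function(sweep_results_by_group,
                                       alpha = 0.05) {
  groups <- names(sweep_results_by_group)
  if (is.null(groups) || any(!nzchar(groups))) {
    stop("groups must be named")
  }
  counts <- lapply(sweep_results_by_group, function(g) {
    if (is.data.frame(g)) {
      if (nrow(g) == 0L) stop("empty group")
      c(selected = sum(g$p < alpha, na.rm = TRUE), total = nrow(g))
    } else {
      if (g$total == 0L) stop("empty group")
      c(selected = g$selected, total = g$total)
    }
  })
  prop <- data.frame(
    group = groups,
    selected = vapply(counts, `[[`, numeric(1), "selected"),
    total = vapply(counts, `[[`, numeric(1), "total"),
    stringsAsFactors = FALSE
  )
  prop$proportion <- prop$selected / prop$total
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  contrasts <- do.call(rbind, lapply(pairs, function(pr) {
    c1 <- counts[[pr[1]]]; c2 <- counts[[pr[2]]]
    tab <- rbind(c(c1["selected"], c1["total"] - c1["selected"]),
                 c(c2["selected"], c2["total"] - c2["selected"]))
    data.frame(group1 = pr[1], group2 = pr[2],
               p = fisher_exact_2x2(tab), stringsAsFactors = FALSE)
  }))
  rownames(prop) <- rownames(contrasts) <- NULL
  list(proportions = prop, contrasts = contrasts)
}
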