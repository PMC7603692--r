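#' Leaf bipartitions of a tree
#'
#' Enumerates the non-trivial leaf bipartitions induced by the internal
#' edges of a tree (treated as unrooted). Each bipartition is canonically
#' represented by the sorted leaf set on the side NOT containing the
#' lexicographically smallest leaf, collapsed to a single string.
#'
#' @param tree An [ape::phylo] tree.
#' @return Character vector of canonical bipartition keys (deduplicated).
#' @export
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(character(0))
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode_tot <- ntip + tr$Nnode
  below <- vector("list", nnode_tot)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  anchor <- min(tree$tip.label)
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= ntip) next # external edge: trivial
    side <- below[[ch]]
    if (anchor %in% side) side <- setdiff(tr$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) next # trivial
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Compare two tree topologies
#'
#' Robinson-Foulds symmetric difference over non-trivial bipartitions, its
#' normalized form, and the shared-edge fraction. Trees are treated as
#' unrooted; with polytomies the normalization denominator is the actual
#' bipartition count `|B1| + |B2|` (which equals `2(n-3)` for binary
#' unrooted trees).
#'
#' @param t1,t2 [ape::phylo] trees. Leaf sets are restricted to their
#'   intersection with a warning if they differ.
#' @return List with `rf`, `normalized_rf`, `shared_edge_fraction`
#'   (`|B1 n B2| / |B1|`), `shared_edge_fraction_rev` (`/ |B2|`),
#'   `n_leaves`.
#' @export
compare_trees <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) {
    stop("fewer than 4 shared leaves; tree comparison undefined")
  }
  if (length(shared) < length(t1$tip.label) ||
      length(shared) < length(t2$tip.label)) {
    warning("leaf sets differ; restricting comparison to ",
            length(shared), " shared leaves")
    t1 <- ape::keep.tip(t1, shared)
    t2 <- ape::keep.tip(t2, shared)
  }
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  ninter <- length(intersect(b1, b2))
  rf <- (length(b1) - ninter) + (length(b2) - ninter)
  denom <- length(b1) + length(b2)
  ntip <- length(shared)
  list(
    rf = rf,
    normalized_rf = if (denom > 0) rf / denom else 0,
    shared_edge_fraction = if (length(b1) > 0) ninter / length(b1) else 1,
    shared_edge_fraction_rev = if (length(b2) > 0) ninter / length(b2)
      else 1,
    # fraction over the full edge set (terminal edges are shared by
    # construction once leaf sets agree), as edge-wise tree comparison
    # tools usually count
    shared_edge_fraction_all = (ntip + ninter) / (ntip + length(b1)),
    n_leaves = ntip
  )
}

# per-edge partition labels, stored on the tree keyed by CHILD node id so
# they survive edge reordering; per-edge view aligned with tree$edge
branch_labels <- function(tree) {
  lab <- tree$branch.label.by.node
  if (is.null(lab)) {
    return(rep("background", nrow(tree$edge)))
  }
  lab[tree$edge[, 2]]
}

set_branch_labels <- function(tree, edge_labels) {
  stopifnot(length(edge_labels) == nrow(tree$edge))
  nmax <- max(tree$edge)
  by_node <- rep(NA_character_, nmax)
  by_node[tree$edge[, 2]] <- edge_labels
  tree$branch.label.by.node <- by_node
  tree
}

#' Label all branches of named clades
#'
#' Attaches branch partition labels (e.g. `"#1"`/`"#2"` or
#' `"Test"`/`"Reference"`) to every internal and external branch of each
#' named monophyletic clade; all remaining branches are labeled
#' `"background"`. The clade's stem branch is excluded by default.
#'
#' @param tree An [ape::phylo] tree.
#' @param clade_spec Named list: label -> character vector of leaf labels
#'   forming a monophyletic group.
#' @param include_stem Also label the stem branch of each clade.
#' @return The tree with branch labels attached (see internal accessor used
#'   by the model fits); inspect with [branch_inventory()].
#' @export
label_clades <- function(tree, clade_spec, include_stem = FALSE) {
  stopifnot(is.list(clade_spec), !is.null(names(clade_spec)))
  ntip <- length(tree$tip.label)
  labels <- rep("background", nrow(tree$edge))
  for (lab in names(clade_spec)) {
    leaves <- clade_spec[[lab]]
    unknown <- setdiff(leaves, tree$tip.label)
    if (length(unknown) > 0L) {
      stop("unknown leaves: ", paste(unknown, collapse = ", "))
    }
    if (length(leaves) == length(tree$tip.label)) {
      labels[] <- lab
      next
    }
    mrca <- ape::getMRCA(tree, leaves)
    clade_tips <- tree$tip.label[unlist(
      descendant_tips(tree, mrca, ntip))]
    intruders <- setdiff(clade_tips, leaves)
    if (length(intruders) > 0L) {
      stop("leaf set for '", lab, "' is not monophyletic; intruding ",
           "leaves: ", paste(intruders, collapse = ", "))
    }
    nodes <- descendant_nodes(tree, mrca)
    in_clade <- tree$edge[, 2] %in% nodes
    if (include_stem) in_clade <- in_clade | tree$edge[, 2] == mrca
    if (any(labels[in_clade] != "background")) {
      stop("clades overlap at label '", lab, "'")
    }
    labels[in_clade] <- lab
  }
  set_branch_labels(tree, labels)
}

# all descendant node ids (internal + tips) strictly below `node`
descendant_nodes <- function(tree, node) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack) > 0L) {
    n <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, n)
    stack <- c(stack, tree$edge[tree$edge[, 1] == n, 2])
  }
  out
}

# tip indices below a node
descendant_tips <- function(tree, node, ntip) {
  nodes <- descendant_nodes(tree, node)
  nodes[nodes <= ntip]
}

#' Extract a subtree and the matching alignment rows
#'
#' Prunes the tree to the named leaves (suppressing degree-2 nodes and
#' summing their branch lengths, so pairwise path lengths are preserved) and
#' subsets the alignment to the same taxa.
#'
#' @param tree An [ape::phylo] tree.
#' @param leaves Leaf labels to retain.
#' @param alignment Optional alignment whose rows (by `id`) cover `leaves`.
#' @return List with `tree` and (if given) `alignment`.
#' @export
extract_subtree <- function(tree, leaves, alignment = NULL) {
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown leaves: ", paste(unknown, collapse = ", "))
  }
  sub <- if (setequal(leaves, tree$tip.label)) tree else
    ape::keep.tip(tree, leaves)
  out <- list(tree = sub)
  if (!is.null(alignment)) {
    idx <- match(sub$tip.label, alignment$id)
    if (anyNA(idx)) {
      stop("alignment missing rows: ",
           paste(sub$tip.label[is.na(idx)], collapse = ", "))
    }
    aln <- alignment[idx, , drop = FALSE]
    rownames(aln) <- NULL
    out$alignment <- aln
  }
  out
}

#' Inventory of branches and their partition labels
#'
#' @param tree A (possibly labeled) [ape::phylo] tree.
#' @return Data frame with one row per branch: `parent`, `child`, `length`,
#'   `label`, `is_external`.
#' @export
branch_inventory <- function(tree) {
  ntip <- length(tree$tip.label)
  data.frame(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    length = if (is.null(tree$edge.length)) NA_real_ else tree$edge.length,
    label = branch_labels(tree),
    is_external = tree$edge[, 2] <= ntip,
    stringsAsFactors = FALSE
  )
}
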