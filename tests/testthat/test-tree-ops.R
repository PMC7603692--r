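test_that("identical trees have RF 0 and full edge sharing", {
  set.seed(2)
  tr <- ape::rtree(10)
  cmp <- compare_trees(tr, tr)
  expect_equal(cmp$rf, 0)
  expect_equal(cmp$normalized_rf, 0)
  expect_equal(cmp$shared_edge_fraction, 1)
})

test_that("maximally different quartets have normalized RF 1", {
  t1 <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- read_newick(text = "((A:1,C:1):1,(B:1,D:1):1);")
  cmp <- compare_trees(t1, t2)
  expect_equal(cmp$normalized_rf, 1)
  expect_equal(cmp$shared_edge_fraction, 0)
})

test_that("RF agrees with phangorn on random binary trees", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:9, 1)
    t1 <- ape::rtree(n)
    t2 <- ape::rtree(n)
    cmp <- compare_trees(t1, t2)
    expect_equal(cmp$rf, as.numeric(phangorn::RF.dist(t1, t2)))
    expect_gte(cmp$normalized_rf, 0)
    expect_lte(cmp$normalized_rf, 1)
    # symmetry
    expect_equal(compare_trees(t2, t1)$rf, cmp$rf)
  }
})

test_that("comparison restricts to shared leaves and needs at least 4", {
  t1 <- read_newick(text = "((A:1,B:1):1,(C:1,(D:1,E:1):1):1);")
  t2 <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_warning(cmp <- compare_trees(t1, t2), "shared")
  expect_equal(cmp$n_leaves, 4)
  t3 <- read_newick(text = "((A:1,B:1):1,C:1);")
  expect_error(suppressWarnings(compare_trees(t1, t3)), "4 shared")
})

test_that("clade labeling covers internal and external branches", {
  tr <- read_newick(
    text = "(((A:1,B:1):1,C:1):1,((D:1,E:1):1,F:1):1);")
  lab <- label_clades(tr, list("#1" = c("A", "B", "C")))
  inv <- branch_inventory(lab)
  expect_equal(sum(inv$label == "#1"), 4) # 3 external + 1 internal
  expect_equal(sum(inv$label == "background"), nrow(inv) - 4)
  lab2 <- label_clades(tr, list("#1" = c("A", "B", "C")),
                       include_stem = TRUE)
  expect_equal(sum(branch_inventory(lab2)$label == "#1"), 5)
  # whole-tree clade labels every branch
  lab3 <- label_clades(tr, list(all = tr$tip.label))
  expect_true(all(branch_inventory(lab3)$label == "all"))
  expect_error(label_clades(tr, list(x = c("A", "D"))),
               "not monophyletic")
  expect_error(label_clades(tr, list(x = c("A", "Z"))), "unknown")
})

test_that("clade of k leaves has 2k-2 branches, stem excluded", {
  set.seed(8)
  tr <- ape::rtree(12)
  ntip <- 12
  node <- tr$edge[tr$edge[, 2] > ntip, 2][3]
  leaves <- tr$tip.label[paraselect:::descendant_tips(tr, node, ntip)]
  k <- length(leaves)
  lab <- label_clades(tr, list("#1" = leaves))
  expect_equal(sum(branch_inventory(lab)$label == "#1"), 2 * k - 2)
})

test_that("subtree extraction preserves pairwise path lengths", {
  set.seed(4)
  for (i in 1:20) {
    tr <- ape::rtree(8)
    keep <- sample(tr$tip.label, sample(3:7, 1))
    sub <- extract_subtree(tr, keep)$tree
    d_full <- ape::cophenetic.phylo(tr)[keep, keep]
    d_sub <- ape::cophenetic.phylo(sub)[keep, keep]
    expect_equal(d_sub, d_full, tolerance = 1e-9)
  }
})

test_that("subtree extraction subsets the alignment to matching rows", {
  tr <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  aln <- data.frame(id = c("D", "C", "B", "A"),
                    residues = c("ATG", "AAA", "TGG", "CCC"))
  out <- extract_subtree(tr, c("A", "C", "D"), aln)
  expect_setequal(out$alignment$id, c("A", "C", "D"))
  expect_equal(out$alignment$residues[out$alignment$id == "A"], "CCC")
  expect_error(extract_subtree(tr, c("A", "Z")), "unknown")
  # identity prune
  expect_equal(extract_subtree(tr, tr$tip.label)$tree$tip.label,
               tr$tip.label)
})

test_that("branch inventory has 2n-3 branches for unrooted binary trees", {
  set.seed(6)
  n <- 9
  tr <- ape::unroot(ape::rtree(n))
  expect_equal(nrow(branch_inventory(tr)), 2 * n - 3)
  expect_equal(sum(branch_inventory(tr)$is_external), n)
})
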