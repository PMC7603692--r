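# Model-level behavior on small datasets; power/calibration at the study
# scale lives in test-acceptance.R.

make_small_m7_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(17)
      tree <- ape::rtree(6, br = function(n) runif(n, 0.08, 0.3))
      sim <- simulate_codon_alignment(
        tree, sim_spec(family = "M7", kappa = 2, p = 0.5, q = 1.5),
        120, seed = 8)
      bl <- fit_m0(sim$alignment, tree)
      cache <<- list(tree = tree, sim = sim, bl = bl)
    }
    cache
  }
})

test_that("M8 log-likelihood dominates M7 (nesting)", {
  d <- make_small_m7_data()
  res <- site_test_m7m8(d$sim$alignment, d$tree, baseline = d$bl)
  expect_gte(res$fit_m8$logL, res$fit_m7$logL)
  expect_gte(res$lrt$statistic, 0)
  expect_true(all(res$sites$posterior >= 0 & res$sites$posterior <= 1))
  expect_equal(nrow(res$sites), 120)
})

test_that("clade model C requires a labeled tree", {
  d <- make_small_m7_data()
  expect_error(fit_clade_model_c(d$sim$alignment, d$tree), "partitions")
})

test_that("RELAX requires Test labels and reports mean omega", {
  d <- make_small_m7_data()
  expect_error(fit_relax(d$sim$alignment, d$tree), "Test")
})

test_that("grid EB posteriors stay near zero on purifying data", {
  d <- make_small_m7_data() # all true omegas < 1
  res <- site_test_grid_eb(d$sim$alignment, d$tree, baseline = d$bl)
  expect_true(all(diff(res$objective_trace) > -1e-6))
  expect_equal(sum(res$weights), 1, tolerance = 1e-9)
  expect_lt(mean(res$sites$posterior), 0.2)
  expect_lt(mean(res$sites$flagged), 0.05)
})

test_that("grid EB on a single site yields a normalized posterior", {
  tree <- quartet_tree()
  sim <- simulate_codon_alignment(tree, sim_spec(omega = 0.2), 1, seed = 2)
  bl <- fit_m0(sim$alignment, tree)
  res <- site_test_grid_eb(sim$alignment, tree, baseline = bl)
  expect_equal(nrow(res$sites), 1)
  expect_gte(res$sites$posterior, 0)
  expect_lte(res$sites$posterior, 1)
})

test_that("a site with zero substitutions is not called episodic", {
  tree <- quartet_tree()
  aln <- codon_alignment(data.frame(
    id = c("A", "B", "C", "D"),
    residues = rep(paste(rep("ATG", 10), collapse = ""), 4)))
  bl <- fit_m0(aln, tree)
  res <- site_test_episodic(aln, tree, baseline = bl)
  expect_true(all(res$p == 1))
  expect_true(all(!res$flagged))
})

test_that("branch test returns p = 1 on zero-length focal branches", {
  tree <- read_newick(text = "((A:0.2,B:0):0.1,(C:0.2,D:0.2):0.1);")
  sim <- simulate_codon_alignment(tree, sim_spec(omega = 0.2), 60, seed = 3)
  bl <- fit_m0(sim$alignment, tree)
  focal <- which(tree$tip.label == "B")
  expect_warning(res <- branch_test_episodic(sim$alignment, tree, focal,
                                             baseline = bl),
                 "zero-length")
  expect_equal(res$lrt$p, 1)
})

test_that("NEB posteriors sum to one per site", {
  d <- make_small_m7_data()
  ntip <- length(d$tree$tip.label)
  kids <- d$tree$edge[d$tree$edge[, 1] == ntip + 1, 2]
  kid_int <- kids[kids > ntip][1]
  c1 <- d$tree$tip.label[paraselect:::descendant_tips(d$tree, kid_int,
                                                      ntip)]
  ltree <- label_clades(d$tree, list("#1" = c1,
                                     "#2" = setdiff(d$tree$tip.label, c1)))
  bl <- d$bl
  bl$td$edge_label <- paraselect:::branch_labels(
    ape::reorder.phylo(ltree, "postorder"))
  null_fit <- fit_m2a_rel(d$sim$alignment, ltree, baseline = bl)
  post <- neb_posteriors(null_fit, d$sim$alignment, ltree, baseline = bl)
  expect_equal(unname(rowSums(post)), rep(1, 120), tolerance = 1e-9)
  # single-class model: posterior 1
  m0post <- neb_posteriors(bl, d$sim$alignment, d$tree, baseline = bl)
  expect_true(all(m0post == 1))
})

test_that("mixture-scaled generators have unit expected rate", {
  pi <- codon_frequencies(mode = "equal")
  rc <- paraselect:::rate_coefs(2.3, pi)
  om <- c(0.05, 1, 2.4)
  w <- c(0.6, 0.2, 0.2)
  rho <- rc[["a"]] + rc[["b"]] * sum(w * om)
  rate <- sum(vapply(seq_along(om), function(i) {
    Qr <- build_rate_matrix(2.3, om[i], pi, scale = FALSE)
    w[i] * -sum(pi * diag(Qr$Q)) / rho
  }, numeric(1)))
  expect_equal(rate, 1, tolerance = 1e-9)
})
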