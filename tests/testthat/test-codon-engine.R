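gc_std <- genetic_code()
pi_eq <- codon_frequencies(mode = "equal")

test_that("GY94 rate matrix has the required structure", {
  Q <- build_rate_matrix(kappa = 2, omega = 0.5, pi = pi_eq)$Q
  expect_equal(unname(rowSums(Q)), rep(0, 61), tolerance = 1e-12)
  # entries only between single-step codons
  expect_equal(Q["ATG", "CCC"], 0)
  expect_gt(Q["ATG", "ATA"], 0)
  # omega = 0 kills all nonsynonymous moves
  Q0 <- build_rate_matrix(2, 0, pi_eq, scale = FALSE)$Q
  expect_equal(Q0["TTT", "TTA"], 0) # F -> L nonsynonymous
  expect_gt(Q0["TTT", "TTC"], 0)    # F -> F synonymous
  expect_error(build_rate_matrix(2, 0.5, pi_eq * 2), "sum to 1")
})

test_that("rate matrix satisfies detailed balance and unit scaling", {
  set.seed(3)
  aln <- simulate_codon_alignment(quartet_tree(), sim_spec(), 40, 5)$alignment
  pi <- codon_frequencies(aln, mode = "F3x4")
  Qr <- build_rate_matrix(1.8, 0.7, pi)
  bal <- pi * Qr$Q
  expect_equal(bal, t(bal), tolerance = 1e-12)
  expect_equal(-sum(pi * diag(Qr$Q)), 1, tolerance = 1e-9)
})

test_that("kappa=omega=1 equal-pi matrix is proportional to adjacency", {
  Q <- build_rate_matrix(1, 1, pi_eq, scale = FALSE)$Q
  off <- Q[row(Q) != col(Q)]
  expect_setequal(round(unique(off), 12), round(c(0, 1 / 61), 12))
})

test_that("transition matrices are stochastic and converge to pi", {
  Qr <- build_rate_matrix(2, 0.4, pi_eq)
  expect_equal(transition_matrix(Qr, 0), diag(61), ignore_attr = TRUE,
               tolerance = 1e-10)
  P <- transition_matrix(Qr, 0.7)
  expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-10)
  Pinf <- transition_matrix(Qr, 50)
  for (i in c(1, 30, 61)) {
    expect_lt(max(abs(Pinf[i, ] - pi_eq)), 1e-5)
  }
  expect_error(transition_matrix(Qr, -1), "negative")
})

test_that("pruning equals brute-force enumeration on quartets", {
  tree <- quartet_tree()
  spec <- sim_spec(family = "M0", kappa = 2, omega = 0.3)
  sim <- simulate_codon_alignment(tree, spec, 12, seed = 42)
  aln <- sim$alignment
  # introduce a gap codon and an ambiguous codon
  aln$residues[1] <- paste0("---", substring(aln$residues[1], 4))
  sub <- substring(aln$residues[2], 1, 3)
  aln$residues[2] <- paste0(substr(sub, 1, 2), "N",
                            substring(aln$residues[2], 4))
  aln <- codon_alignment(aln)
  for (pars in list(list(k = 2, om = 0.3, w = 1),
                    list(k = 1.5, om = c(0.1, 1, 2.5),
                         w = c(0.6, 0.3, 0.1)))) {
    ll_pkg <- pkg_mixture_loglik(aln, tree, pars$k, pi_eq, pars$om,
                                 pars$w)
    ll_or <- oracle_quartet_loglik(aln, tree, pars$k, pi_eq, pars$om,
                                   pars$w)
    expect_equal(ll_pkg, ll_or, tolerance = 1e-8)
  }
})

test_that("an all-gap site contributes zero log-likelihood", {
  tree <- quartet_tree()
  aln <- codon_alignment(data.frame(
    id = c("A", "B", "C", "D"),
    residues = c("ATG---", "ATG---", "ATG---", "ATG---")))
  td <- paraselect:::prepare_tipdata(aln, tree)
  lm <- paraselect:::layer_logliks(td, 2, pi_eq,
                                   list(list(omega = 0.3, scale = 1)))
  gap_pat <- td$pattern_of_site[2]
  expect_equal(lm[gap_pat, 1], 0, tolerance = 1e-12)
})

test_that("LRT p values follow the chi-square reference", {
  f0 <- structure(list(logL = -100), class = "codon_fit")
  f1 <- structure(list(logL = -100), class = "codon_fit")
  expect_equal(lrt(f0, f1, df = 1)$p, 1)
  f2 <- structure(list(logL = -100 + 3.84 / 2), class = "codon_fit")
  expect_equal(lrt(f0, f2, df = 1)$p, 0.05, tolerance = 0.002)
  f3 <- structure(list(logL = -100 + 5.99 / 2), class = "codon_fit")
  expect_equal(lrt(f0, f3, df = 2)$p, 0.05, tolerance = 0.002)
  # boundary mixture: zero statistic gives p 1, mass splits otherwise
  expect_equal(lrt(f0, f1, mixture = list(weights = c(.5, .5),
                                          dfs = c(0, 1)))$p, 1)
  expect_error(lrt(f0, f1), "df")
})

test_that("uniform beta discretization gives decile midpoints", {
  om <- paraselect:::beta_bin_omegas(1, 1, 10)
  expect_equal(om, seq(0.05, 0.95, by = 0.1))
})

test_that("stick-breaking transforms round-trip on the simplex", {
  set.seed(9)
  for (i in 1:50) {
    w <- as.vector(stats::rgamma(3, 1))
    w <- w / sum(w)
    x <- paraselect:::stick_break_inv(w)
    expect_equal(paraselect:::stick_break(x), w, tolerance = 1e-6)
  }
})

test_that("M0 fit recovers parameters and is deterministic", {
  set.seed(31)
  tree <- ape::rtree(6, br = function(n) runif(n, 0.08, 0.3))
  sim <- simulate_codon_alignment(tree, sim_spec(kappa = 2, omega = 0.3),
                                  200, seed = 13)
  f1 <- fit_m0(sim$alignment, tree)
  f2 <- fit_m0(sim$alignment, tree)
  expect_identical(f1$logL, f2$logL) # bit-for-bit reproducible
  expect_gt(f1$mle$omega, 0.15)
  expect_lt(f1$mle$omega, 0.5)
  expect_true(f1$converged)
})

test_that("invariant alignments are flagged as unidentifiable", {
  tree <- quartet_tree()
  aln <- codon_alignment(data.frame(
    id = c("A", "B", "C", "D"),
    residues = rep(strrep("ATGAAATGG", 3), 4)))
  f <- fit_m0(aln, tree)
  expect_false(f$identifiable)
  expect_lt(f$mle$scale, 1e-5)
})
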