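test_that("rpkm follows the formula and its scaling identities", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(10, 1000, 2e6), 5)   # doubling library halves
  expect_equal(rpkm(10, 2000, 1e6), 5)   # doubling length halves
  expect_equal(rpkm(20, 1000, 1e6), 20)  # linear in counts
  m <- matrix(c(10, 20, 30, 40), 2)
  out <- rpkm(m, c(1000, 2000), c(1e6, 2e6))
  expect_equal(out[1, 1], 10)
  expect_equal(out[2, 2], 10)
  expect_error(rpkm(10, 0, 1e6), "positive")
  expect_error(rpkm(10, 1000, 0), "positive")
})

test_that("pearson_with_p matches the closed-form calculation", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 7)
  res <- pearson_with_p(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_stat <- r_hand * sqrt(1 / (1 - r_hand^2))  # n - 2 = 1 df
  expect_equal(res$p, 2 * pt(-abs(t_stat), df = 1), tolerance = 1e-10)
  expect_equal(pearson_with_p(x, x)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  expect_error(pearson_with_p(x, c(1, 1, 1)), "variance")
  expect_error(pearson_with_p(1:2, 1:2), "3 observations")
})

make_tab <- function(gene, reads, tissues = paste0("t", seq_along(reads)),
                     len = 1000, lib = 1e6) {
  data.frame(gene = gene, tissue = tissues, reads = reads,
             gene_length = len, library_size = lib,
             stringsAsFactors = FALSE)
}

test_that("correlation panel computes the four comparisons", {
  reads <- c(10, 40, 90, 160, 250, 360)
  a <- make_tab("a", reads)
  b <- make_tab("b", rev(reads))
  o <- make_tab("o", reads, len = 2000)
  panel <- correlation_panel(a, b, o)
  expect_equal(nrow(panel), 4)
  # copy a is proportional to the outgroup profile
  expect_equal(panel$r[panel$comparison == "a_vs_outgroup"], 1)
  expect_equal(panel$significance[panel$comparison == "a_vs_outgroup"],
               "**")
  expect_equal(panel$r[panel$comparison == "a_vs_b"],
               cor(reads, rev(reads)))
})

test_that("panel is invariant to tissue ordering and symmetric in copies", {
  set.seed(21)
  reads_a <- rpois(8, 100); reads_b <- rpois(8, 100)
  reads_o <- rpois(8, 100)
  a <- make_tab("a", reads_a); b <- make_tab("b", reads_b)
  o <- make_tab("o", reads_o)
  perm <- sample(8)
  p1 <- correlation_panel(a, b, o)
  p2 <- correlation_panel(a[perm, ], b, o)
  expect_equal(p1$r, p2$r, tolerance = 1e-12)
  p_ba <- correlation_panel(b, a, o)
  expect_equal(p1$r[p1$comparison == "a_vs_b"],
               p_ba$r[p_ba$comparison == "a_vs_b"], tolerance = 1e-12)
})

test_that("an extreme shared tissue drives significance; exclusion flips it", {
  # mirror of the testis observation: one huge shared outlier makes the
  # correlation with the outgroup significant; dropping it removes that
  base_a <- c(5, 9, 7, 6, 8, 5, 7)
  base_o <- c(7, 9, 8, 8, 3, 7, 3)  # uncorrelated with base_a (p ~ 0.8)
  a <- make_tab("a", c(base_a, 5000),
                tissues = c(paste0("t", 1:7), "testis"))
  b <- make_tab("b", c(rev(base_a), 4500),
                tissues = c(paste0("t", 1:7), "testis"))
  o <- make_tab("o", c(base_o, 6000),
                tissues = c(paste0("t", 1:7), "testis"))
  with_testis <- correlation_panel(a, b, o)
  without <- correlation_panel(a, b, o, exclude_tissues = "testis")
  r_with <- with_testis[with_testis$comparison == "a_vs_outgroup", ]
  r_without <- without[without$comparison == "a_vs_outgroup", ]
  expect_lt(r_with$p, 0.05)
  expect_gt(r_without$p, 0.05)
  expect_false("testis" %in% attr(without, "tissues_used"))
})

test_that("panel needs at least 3 shared tissues", {
  a <- make_tab("a", c(1, 2, 3, 4))
  b <- make_tab("b", c(4, 3, 2, 1))
  o <- make_tab("o", c(2, 3, 4, 5))
  expect_error(correlation_panel(a, b, o,
                                 exclude_tissues = c("t1", "t2")),
               "fewer than 3")
})

test_that("expression tables read back from TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", paste("gene", "tissue", "reads",
                                  "gene_length", "library_size",
                                  sep = "\t"),
               paste("g1", "liver", "10", "1000", "1000000",
                     sep = "\t")), f)
  tb <- read_expression_table(f)
  expect_equal(tb$reads, 10)
  expect_error(read_expression_table(
    {f2 <- withr::local_tempfile(fileext = ".tsv")
     writeLines("gene\ttissue", f2); f2}), "lacks")
})
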