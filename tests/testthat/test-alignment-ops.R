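prot_aln <- function(rows) {
  protein_alignment(data.frame(id = paste0("s", seq_along(rows)),
                               description = "", residues = rows,
                               stringsAsFactors = FALSE))
}

test_that("average ungapped length is the arithmetic mean", {
  recs <- data.frame(residues = c("MKVL", "MK-VLA", "MKVLAW"))
  expect_equal(average_ungapped_length(recs), 5)
  expect_equal(average_ungapped_length(data.frame(residues = "MKVLMKVLMK")),
               10)
})

test_that("short-sequence filter is two-pass", {
  recs <- data.frame(id = 1:4, residues = c(strrep("M", 100),
                                            strrep("K", 100),
                                            strrep("V", 100),
                                            strrep("W", 10)))
  out <- filter_short_sequences(recs)
  expect_equal(nrow(out$kept), 3)
  expect_equal(nrow(out$excluded), 1)
  expect_equal(out$final_average, 100)
  # cutoff below both: mean 75, cutoff 45 keeps both
  out2 <- filter_short_sequences(
    data.frame(id = 1:2, residues = c(strrep("M", 50), strrep("M", 100))))
  expect_equal(nrow(out2$kept), 2)
  # all equal: nothing dropped
  out3 <- filter_short_sequences(
    data.frame(id = 1:3, residues = rep(strrep("M", 20), 3)))
  expect_equal(nrow(out3$excluded), 0)
  expect_equal(out3$final_average, 20)
})

test_that("trimming removes all-gap columns first and hits the target", {
  a <- prot_aln(c("MK-VL-W", "MK-VL-W", "MA-VD-W"))
  tr <- trim_to_average(a, 5)
  expect_equal(attr(tr, "n_columns"), 5L)
  expect_equal(attr(tr, "kept_columns"), c(1L, 2L, 4L, 5L, 7L))
  expect_equal(tr$residues[1], "MKVLW")
  # identity when target equals width
  tr2 <- trim_to_average(a, 7)
  expect_equal(tr2$residues, a$residues)
  expect_error(trim_to_average(a, 0), "positive")
  expect_error(trim_to_average(a, 9), "exceeds")
})

test_that("gapless trimming removes rightmost columns (tie-break)", {
  a <- prot_aln(c("MKVLW", "MKVLW"))
  tr <- trim_to_average(a, 3)
  expect_equal(attr(tr, "kept_columns"), 1:3)
})

test_that("trimming never removes a less-gappy column before a gappier one", {
  set.seed(42)
  for (i in 1:200) {
    a <- random_protein_alignment(sample(2:6, 1), sample(4:12, 1))
    ncols <- attr(a, "n_columns")
    target <- sample(seq_len(ncols - 1), 1)
    tr <- trim_to_average(a, target)
    expect_equal(attr(tr, "n_columns"), target)
    gf <- column_profile(a)$gap_fraction
    kept <- attr(tr, "kept_columns")
    removed <- setdiff(seq_len(ncols), kept)
    # removed gap fractions are exactly the top-k of the multiset
    expect_equal(sort(gf[removed]),
                 sort(sort(gf, decreasing = TRUE)[seq_along(removed)]))
  }
})

test_that("consensus avoids gaps and breaks ties alphabetically", {
  a <- prot_aln(c("AA-", "AC-", "-CC"))
  # col1 {A,A,-} -> A; col2 {A,C,C} -> C; col3 {-,-,C} -> C
  cons <- consensus(a)
  expect_equal(cons$residues, "ACC")
  # tie A vs C -> A
  expect_equal(consensus(prot_aln(c("A", "C")))$residues, "A")
  expect_error(consensus(prot_aln(c("-", "-"))), "entirely gaps")
})

test_that("consensus of a gapless single row is that row", {
  set.seed(7)
  for (i in 1:100) {
    a <- random_protein_alignment(1, sample(5:30, 1), gap_prob = 0)
    expect_equal(consensus(a)$residues, a$residues[1])
  }
})

test_that("back-translation inverts translation", {
  a <- prot_aln(c("M-K", "MWK"))
  cds <- data.frame(id = c("s1", "s2"),
                    residues = c("ATGAAA", "ATGTGGAAG"))
  ca <- back_translate(a, cds)
  expect_equal(ca$residues, c("ATG---AAA", "ATGTGGAAG"))
  expect_equal(vapply(ca$residues, translate_codons, ""),
               setNames(a$residues, ca$residues), ignore_attr = TRUE)
  # mismatching CDS errors with position
  cds_bad <- data.frame(id = c("s1", "s2"),
                        residues = c("ATGCCC", "ATGTGGAAG"))
  expect_error(back_translate(a, cds_bad), "mismatch")
})

test_that("translate(back_translate(x)) recovers rows on random fixtures", {
  set.seed(11)
  for (i in 1:100) {
    a <- random_protein_alignment(sample(2:5, 1), sample(4:20, 1),
                                  gap_prob = 0.2)
    cds <- data.frame(
      id = a$id,
      residues = vapply(a$residues, cds_for_protein, character(1)),
      stringsAsFactors = FALSE
    )
    ca <- back_translate(a, cds)
    back <- vapply(ca$residues, translate_codons, character(1))
    expect_equal(unname(back), a$residues)
  }
})

test_that("back-translation of a trimmed alignment uses source codons", {
  full <- prot_aln(c("MK-V", "MKWV"))
  cds <- data.frame(id = c("s1", "s2"),
                    residues = c(cds_for_protein("MKV"),
                                 cds_for_protein("MKWV")))
  tr <- trim_to_average(full, 3) # drops the gappy column 3
  ca <- back_translate(tr, cds, kept_columns = attr(tr, "kept_columns"),
                       full_alignment = full)
  expect_equal(unname(vapply(ca$residues, translate_codons, character(1))),
               tr$residues)
})

test_that("site-to-domain mapping groups by interval and merges tags", {
  dom <- data.frame(name = c("zf-TAZ", "KIX"),
                    start = c(350, 560), end = c(430, 640))
  sites <- data.frame(site = c(397, 100, 600, 397, 500),
                      method = c("E", "E", "M", "F", "E"))
  mp <- map_sites_to_domains(sites, dom, consensus_length = 1000)
  expect_equal(mp$region[mp$site == 397], "zf-TAZ")
  expect_equal(mp$methods[mp$site == 397], "EF")
  expect_equal(mp$region[mp$site == 100], "before zf-TAZ")
  expect_equal(mp$region[mp$site == 500], "before KIX")
  expect_equal(mp$region[mp$site == 600], "KIX")
  expect_error(map_sites_to_domains(sites,
    data.frame(name = c("a", "b"), start = c(1, 5), end = c(10, 20)),
    1000), "overlap")
  expect_error(map_sites_to_domains(data.frame(site = 2000, method = "E"),
                                    dom, 1000), "outside")
})
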