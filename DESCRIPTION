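Package: paraselect
Title: Selection Analysis of Whole-Genome-Duplication Paralogs with Codon Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the divergence of gene duplicates retained
    after whole-genome duplication, built around the Ep300a/Ep300b paralog
    pair of teleost fishes. Implements homolog curation from blast-style hit
    tables, alignment trimming and consensus building, protein-to-codon
    back-translation, Robinson-Foulds tree comparison, GY94-type codon
    substitution models with maximum-likelihood fitting (M0, M7/M8, M2a_rel,
    clade model C, a RELAX-style selection-intensity test, and simplified
    branch- and site-level episodic tests), empirical-Bayes detection of
    positively selected sites, site-to-domain mapping, Fisher-exact branch
    proportion contrasts, and RPKM-based tissue-expression correlation of
    paralog pairs. A seedable simulator generates codon alignments and
    expression tables with known ground truth for every supported regime.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
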