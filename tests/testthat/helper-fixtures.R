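# Shared fixtures and independent oracles for the test suite.

quartet_tree <- function(ta = 0.3, tb = 0.2, tc = 0.25, td = 0.1,
                         t1 = 0.15, t2 = 0.05) {
  read_newick(text = sprintf(
    "((A:%g,B:%g):%g,(C:%g,D:%g):%g);", ta, tb, t1, tc, td, t2))
}

# Brute-force likelihood oracle for a quartet ((A,B),(C,D)): explicit sum
# over the 61 x 61 interior-node states, mixed over site classes.
# Independent of the pruning kernel (plain R matrix algebra).
oracle_quartet_loglik <- function(alignment, tree, kappa, pi, omegas,
                                  weights, code = genetic_code()) {
  stopifnot(length(tree$tip.label) == 4)
  rc_a <- sum_rate_coefs(kappa, pi, code)
  rho <- rc_a[["a"]] + rc_a[["b"]] * sum(weights * omegas)
  chl <- tree$edge[, 2]
  len_of <- function(label) {
    tree$edge.length[chl == which(tree$tip.label == label)]
  }
  ntip <- 4
  # the central edge joining the two cherries (root edges summed)
  t_mid <- sum(tree$edge.length[chl > ntip])
  sense <- code$sense_codons
  tip_vec <- function(cd) {
    v <- numeric(61)
    if (cd == "---") {
      v[] <- 1
    } else if (cd %in% sense) {
      v[match(cd, sense)] <- 1
    } else {
      comp <- intersect(paraselect:::expand_ambiguous_codon(cd), sense)
      v[match(comp, sense)] <- 1
    }
    v
  }
  rows <- setNames(alignment$residues, alignment$id)
  cods <- lapply(rows, paraselect:::codon_split)
  S <- length(cods[[1]])
  total <- 0
  for (s in seq_len(S)) {
    site_lik <- 0
    for (k in seq_along(omegas)) {
      Q <- build_rate_matrix(kappa, omegas[k], pi, code = code,
                             scale = FALSE)
      P <- function(t) transition_matrix(Q, t / rho)
      va <- P(len_of("A")) %*% tip_vec(cods[["A"]][s])
      vb <- P(len_of("B")) %*% tip_vec(cods[["B"]][s])
      vc <- P(len_of("C")) %*% tip_vec(cods[["C"]][s])
      vd <- P(len_of("D")) %*% tip_vec(cods[["D"]][s])
      u_side <- pi * va[, 1] * vb[, 1]
      v_side <- vc[, 1] * vd[, 1]
      lik <- as.numeric(u_side %*% transition_matrix(Q, t_mid / rho) %*%
                          v_side)
      site_lik <- site_lik + weights[k] * lik
    }
    total <- total + log(site_lik)
  }
  total
}

sum_rate_coefs <- function(kappa, pi, code) {
  paraselect:::rate_coefs(kappa, pi, code)
}

# package-side total log-likelihood for the same mixture description
pkg_mixture_loglik <- function(alignment, tree, kappa, pi, omegas,
                               weights, code = genetic_code()) {
  td <- paraselect:::prepare_tipdata(alignment, tree, code)
  rc <- paraselect:::rate_coefs(kappa, pi, code)
  rho <- rc[["a"]] + rc[["b"]] * sum(weights * omegas)
  layers <- lapply(omegas, function(w) list(omega = w, scale = 1 / rho))
  lm <- paraselect:::layer_logliks(td, kappa, pi, layers)
  paraselect:::mixture_loglik(lm, weights, td$pattern_weight)
}

random_protein_alignment <- function(nrow, ncol, gap_prob = 0.15) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- vapply(seq_len(nrow), function(i) {
    chars <- sample(aa, ncol, replace = TRUE)
    gaps <- runif(ncol) < gap_prob
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  # guard: no all-gap row
  rows <- ifelse(grepl("^[-]+$", rows),
                 paste(sample(aa, ncol, replace = TRUE), collapse = ""),
                 rows)
  protein_alignment(data.frame(id = paste0("s", seq_len(nrow)),
                               description = "", residues = rows,
                               stringsAsFactors = FALSE))
}

# random in-frame CDS whose translation is the ungapped protein row
cds_for_protein <- function(prot_row, code = genetic_code()) {
  aas <- strsplit(gsub("-", "", prot_row), "")[[1]]
  by_aa <- split(names(code$aa[code$aa != "*"]), code$aa[code$aa != "*"])
  paste(vapply(aas, function(a) sample(by_aa[[a]], 1), character(1)),
        collapse = "")
}

balanced_newick <- function(labels) {
  build <- function(lab) {
    n <- length(lab)
    if (n == 1) return(lab)
    if (n == 2) return(sprintf("(%s,%s)", lab[1], lab[2]))
    mid <- floor(n / 2)
    sprintf("(%s,%s)", build(lab[seq_len(mid)]), build(lab[-seq_len(mid)]))
  }
  paste0(build(labels), ";")
}
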