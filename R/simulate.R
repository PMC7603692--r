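# Synthetic-data generators: codon alignments under every supported
# selection regime, paralog expression tables, and curation fixtures. Each
# is a pure function of (parameters, seed); the seed and full truth are
# recorded in the output.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Model specification for the codon simulator
#'
#' @param family One of `"M0"`, `"M7"`, `"M8"`, `"M2a_rel"`, `"CmC"`,
#'   `"RELAX"`.
#' @param kappa Transition/transversion ratio.
#' @param omega M0 omega.
#' @param p,q Beta shape parameters (M7/M8).
#' @param p0 Weight of the beta part (M8) .
#' @param omega_s M8 spike omega (>= 1).
#' @param omegas Class omegas `c(omega0, 1, omega2)` for M2a_rel/RELAX.
#' @param props Class proportions (M2a_rel/CmC/RELAX).
#' @param omega2_by_partition Named vector of class-2 omegas per branch
#'   partition (CmC), e.g. `c(background = .3, "#1" = .2, "#2" = .5)`.
#' @param k Selection-intensity exponent applied to the `Test` partition
#'   (RELAX).
#' @param n_categories Beta discretization bins.
#' @return A list of class `codon_sim_spec`.
#' @export
sim_spec <- function(family = "M0", kappa = 2, omega = 0.3,
                     p = 0.5, q = 1.5, p0 = 0.9, omega_s = 4,
                     omegas = c(0.05, 1, 0.5), props = c(0.55, 0.05, 0.4),
                     omega2_by_partition = NULL, k = 1,
                     n_categories = 10L) {
  structure(as.list(environment()), class = "codon_sim_spec")
}

# per-site class omegas and weights implied by a spec; returns list with
# omegas (vector or matrix class x partition), weights, partitions
sim_classes <- function(spec, partitions = "background") {
  fam <- spec$family
  if (fam == "M0") {
    return(list(omegas = matrix(spec$omega, 1, length(partitions),
                                dimnames = list(NULL, partitions)),
                weights = 1))
  }
  if (fam == "M7" || fam == "M8") {
    om <- beta_bin_omegas(spec$p, spec$q, spec$n_categories)
    w <- rep(1 / spec$n_categories, spec$n_categories)
    if (fam == "M8") {
      om <- c(om, spec$omega_s)
      w <- c(w * spec$p0, 1 - spec$p0)
    }
    return(list(omegas = matrix(om, length(om), length(partitions),
                                dimnames = list(NULL, partitions)),
                weights = w))
  }
  if (fam == "M2a_rel") {
    return(list(omegas = matrix(spec$omegas, 3, length(partitions),
                                dimnames = list(NULL, partitions)),
                weights = spec$props))
  }
  if (fam == "CmC") {
    if (is.null(spec$omega2_by_partition)) {
      stop("CmC simulation needs omega2_by_partition")
    }
    missing <- setdiff(partitions, names(spec$omega2_by_partition))
    if (length(missing) > 0L) {
      stop("no omega2 for partition(s): ", paste(missing, collapse = ", "))
    }
    om <- sapply(partitions, function(p) {
      c(spec$omegas[1], 1, spec$omega2_by_partition[[p]])
    })
    return(list(omegas = matrix(om, nrow = 3,
                                dimnames = list(NULL, partitions)),
                weights = spec$props))
  }
  if (fam == "RELAX") {
    om <- sapply(partitions, function(pt) {
      base <- c(spec$omegas[1], 1, spec$omegas[3])
      if (pt == "Test") pmin(base^spec$k, 50) else base
    })
    return(list(omegas = matrix(om, nrow = 3,
                                dimnames = list(NULL, partitions)),
                weights = spec$props))
  }
  stop("unknown family: ", fam)
}

#' Simulate a codon alignment along a tree
#'
#' Draws a site class for every codon from the model's class proportions,
#' the root codon from the stationary frequencies, and evolves it along the
#' tree using the transition matrix of the branch's partition and the
#' site's class (per-partition mixture-rate normalization, matching the
#' fitting side). Only sense codons are ever emitted.
#'
#' @param tree [ape::phylo] tree with branch lengths in expected
#'   substitutions per codon site; must carry partition labels (see
#'   [label_clades()]) for partitioned families (CmC/RELAX).
#' @param spec A [sim_spec()].
#' @param n_codons Number of codon sites.
#' @param seed Integer seed; identical seeds give identical output.
#' @param pi Codon frequencies (default equal over sense codons).
#' @param code A [genetic_code()].
#' @return List with `alignment` (a [codon_alignment()]) and `truth`
#'   (spec, per-site `site_class` and `site_omega` (background partition),
#'   partitions, seed, tree).
#' @export
simulate_codon_alignment <- function(tree, spec, n_codons, seed,
                                     pi = NULL, code = genetic_code()) {
  stopifnot(n_codons >= 1L)
  labs <- branch_labels(tree)
  partitions <- sort(unique(labs))
  if (spec$family %in% c("CmC", "RELAX") && length(partitions) < 2L) {
    stop(spec$family, " simulation needs a partition-labeled tree")
  }
  if (is.null(pi)) pi <- codon_frequencies(mode = "equal", code = code)
  cls <- sim_classes(spec, partitions)
  nclass <- length(cls$weights)
  rc <- rate_coefs(spec$kappa, pi, code)
  rho <- vapply(partitions, function(p) {
    rc[["a"]] + rc[["b"]] * sum(cls$weights * cls$omegas[, p])
  }, numeric(1))

  post <- ape::reorder.phylo(tree, "postorder")
  post_labs <- branch_labels(post)
  ntip <- length(post$tip.label)
  root <- ntip + 1L
  nnode_tot <- ntip + post$Nnode
  # preorder: reverse postorder edge order
  edges_pre <- rev(seq_len(nrow(post$edge)))
  # eigen systems cached per unique omega (kappa, pi fixed)
  uom <- sort(unique(as.vector(cls$omegas)))
  eig <- lapply(uom, function(w) {
    Qr <- build_rate_matrix(spec$kappa, w, pi, code = code, scale = FALSE)
    eigen_reversible(Qr$Q, pi)
  })
  pmat <- function(w, t_eff) {
    es <- eig[[match(w, uom)]]
    P <- es$A %*% (exp(es$lambda * t_eff) * es$B)
    P[P < 0] <- 0
    P / rowSums(P)
  }

  with_seed(seed, {
    site_class <- sample.int(nclass, n_codons, replace = TRUE,
                             prob = cls$weights)
    states <- matrix(NA_integer_, nnode_tot, n_codons)
    states[root, ] <- sample.int(length(pi), n_codons, replace = TRUE,
                                 prob = pi)
    for (e in edges_pre) {
      par <- post$edge[e, 1]
      ch <- post$edge[e, 2]
      pt <- post_labs[e]
      t_eff <- post$edge.length[e] / rho[[pt]]
      for (cl in seq_len(nclass)) {
        idx <- which(site_class == cl)
        if (length(idx) == 0L) next
        P <- pmat(cls$omegas[cl, pt], t_eff)
        from <- states[par, idx]
        for (st in unique(from)) {
          sel <- idx[from == st]
          states[ch, sel] <- sample.int(length(pi), length(sel),
                                        replace = TRUE, prob = P[st, ])
        }
      }
    }
    sense <- code$sense_codons
    rows <- vapply(seq_len(ntip), function(i) {
      paste(sense[states[i, ]], collapse = "")
    }, character(1))
    aln <- codon_alignment(data.frame(
      id = post$tip.label, description = "",
      residues = rows, stringsAsFactors = FALSE
    ), code = code)
    bg <- if ("background" %in% partitions) "background" else partitions[1]
    truth <- list(
      spec = spec,
      site_class = site_class,
      site_omega = cls$omegas[site_class, bg],
      class_omegas = cls$omegas,
      class_weights = cls$weights,
      partitions = partitions,
      seed = seed,
      tree = tree
    )
    list(alignment = aln, truth = truth)
  })
}

#' Simulate paralog expression tables
#'
#' Emulates tissue read-count tables for a duplicate pair plus a
#' non-duplicated outgroup gene: a shared log-mean tissue profile with
#' per-copy lognormal noise; the designated fast-evolving copy gets a
#' positive log-fold shift in a chosen fraction of tissues; counts are
#' negative-binomial.
#'
#' @param n_tissues Number of tissues (>= 4).
#' @param effect_size Log-fold shift of the fast copy (default log(3)).
#' @param effect_fraction Fraction of tissues shifted, in (0, 1\].
#' @param fast_copy `"a"` or `"b"`.
#' @param noise_sd Lognormal noise sd (default 0.3).
#' @param dispersion Negative-binomial dispersion (default 0.1; variance =
#'   mu + dispersion * mu^2).
#' @param base_mean Mean read count scale (default 200).
#' @param seed Integer seed.
#' @return List of expression tables `copy_a`, `copy_b`, `outgroup` (long
#'   format as in [read_expression_table()]) and `truth` (fast copy,
#'   shifted tissues, seed).
#' @export
simulate_expression_tables <- function(n_tissues = 10, effect_size = log(3),
                                       effect_fraction = 0.5,
                                       fast_copy = "a", noise_sd = 0.3,
                                       dispersion = 0.1, base_mean = 200,
                                       seed = 1) {
  stopifnot(n_tissues >= 4L)
  if (effect_fraction <= 0 || effect_fraction > 1) {
    stop("effect_fraction must be in (0, 1]")
  }
  with_seed(seed, {
    tissues <- paste0("tissue", seq_len(n_tissues))
    shared <- stats::rnorm(n_tissues, mean = log(base_mean), sd = 1)
    n_shift <- max(1L, round(effect_fraction * n_tissues))
    shifted <- sort(sample.int(n_tissues, n_shift))
    gene_lengths <- c(a = 7200, b = 7050, out = 7400)
    lib_size <- round(stats::runif(n_tissues, 2e7, 4e7))
    draw <- function(lmu) {
      mu <- exp(lmu + stats::rnorm(n_tissues, 0, noise_sd))
      if (dispersion > 0) {
        stats::rnbinom(n_tissues, mu = mu, size = 1 / dispersion)
      } else {
        round(mu)
      }
    }
    lmu_a <- shared + if (fast_copy == "a")
      ifelse(seq_len(n_tissues) %in% shifted, effect_size, 0) else 0
    lmu_b <- shared + if (fast_copy == "b")
      ifelse(seq_len(n_tissues) %in% shifted, effect_size, 0) else 0
    mk <- function(gene, counts, len) {
      data.frame(gene = gene, tissue = tissues, reads = counts,
                 gene_length = len, library_size = lib_size,
                 stringsAsFactors = FALSE)
    }
    list(
      copy_a = mk("copy_a", draw(lmu_a), gene_lengths[["a"]]),
      copy_b = mk("copy_b", draw(lmu_b), gene_lengths[["b"]]),
      outgroup = mk("outgroup", draw(shared), gene_lengths[["out"]]),
      truth = list(fast_copy = fast_copy, shifted_tissues = shifted,
                   seed = seed)
    )
  })
}

#' Generate a homolog-curation fixture with known expected selection
#'
#' Emits a blast-style hit table (including decoy hits lacking the keyword
#' and hits from disallowed organisms), a matching gene table with mixed
#' statuses, and the per-gene selection implied by the curation rules.
#'
#' @param seed Integer seed.
#' @param n_genes Number of true genes (default 6).
#' @param keyword Description keyword (default `"p300"`).
#' @return List with `hits`, `genes` (data frames), `keyword`,
#'   `allowed_organisms`, and `expected` (gene_id -> protein_accession).
#' @export
make_curation_fixture <- function(seed = 1, n_genes = 6,
                                  keyword = "p300") {
  with_seed(seed, {
    organisms <- paste0("Species_", LETTERS[seq_len(n_genes)])
    decoy_orgs <- c("Offtarget_X", "Offtarget_Y")
    hits <- list(); genes <- list(); expected <- list()
    rank <- 0L
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%03d", g)
      n_iso <- sample(1:3, 1)
      statuses <- sample(c("MODEL", "PREDICTED", "PROVISIONAL"), n_iso,
                         replace = TRUE)
      if (stats::runif(1) < 0.5) {
        statuses[sample.int(n_iso, 1)] <- "VALIDATED"
      }
      accs <- sprintf("XP_%03d%02d.1", g, seq_len(n_iso))
      rnk <- rank + sample.int(n_iso)
      rank <- rank + n_iso
      for (i in seq_len(n_iso)) {
        hits[[length(hits) + 1L]] <- data.frame(
          rank = rnk[i], hit_accession = accs[i],
          description = paste("histone acetyltransferase", keyword,
                              "isoform", i),
          organism = organisms[g], bitscore = 2500 - rnk[i],
          evalue = 10^(-200 + rnk[i]), stringsAsFactors = FALSE)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, species = organisms[g], status = statuses[i],
          protein_accession = accs[i], stringsAsFactors = FALSE)
      }
      ord <- order(rnk, accs)
      val <- which(statuses == "VALIDATED")
      pick <- if (length(val) > 0L) {
        vord <- val[order(rnk[val], accs[val])]
        accs[vord[1]]
      } else {
        accs[ord[1]]
      }
      expected[[gid]] <- pick
    }
    # decoys: keyword absent or disallowed organism
    rank <- rank + 1L
    hits[[length(hits) + 1L]] <- data.frame(
      rank = rank, hit_accession = "XP_900001.1",
      description = "CREB binding protein", organism = organisms[1],
      bitscore = 900, evalue = 1e-50, stringsAsFactors = FALSE)
    rank <- rank + 1L
    hits[[length(hits) + 1L]] <- data.frame(
      rank = rank, hit_accession = "XP_900002.1",
      description = paste("uncharacterized", keyword, "like protein"),
      organism = decoy_orgs[1], bitscore = 800, evalue = 1e-40,
      stringsAsFactors = FALSE)
    hits_df <- do.call(rbind, hits)
    hits_df <- hits_df[order(hits_df$rank), ]
    rownames(hits_df) <- NULL
    list(
      hits = hits_df,
      genes = do.call(rbind, genes),
      keyword = keyword,
      allowed_organisms = organisms,
      expected = unlist(expected)
    )
  })
}
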