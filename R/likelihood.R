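# Likelihood engine: tip-state preparation, site-pattern compression and the
# bridge to the C++ pruning kernel. Model-level code describes a fit as a set
# of site-class "layers"; each layer gives the omega used on every edge
# (optionally a two-omega per-branch mixture for episodic models) and an
# effective rate scaling per edge.

# Convert alignment + tree into kernel-ready tip data with site patterns
# collapsed. Returns edge matrix in postorder, tip partial cube over unique
# patterns, pattern weights, and the pattern index of every original site.
prepare_tipdata <- function(alignment, tree, code = genetic_code()) {
  if (!setequal(tree$tip.label, alignment$id)) {
    stop("tree leaves and alignment rows do not match")
  }
  sense <- code$sense_codons
  n <- length(sense)
  ntip <- length(tree$tip.label)
  rows <- alignment$residues[match(tree$tip.label, alignment$id)]
  S <- nchar(rows[1]) %/% 3L
  codmat <- vapply(rows, function(r) codon_split(toupper(r)),
                   character(S)) # S x ntip
  if (S == 1L) codmat <- matrix(codmat, nrow = 1L)
  # pattern compression
  keys <- apply(codmat, 1, paste, collapse = " ")
  upat <- !duplicated(keys)
  pat_of_site <- match(keys, keys[upat])
  pat_rows <- which(upat)
  npat <- length(pat_rows)
  tipL <- array(0, dim = c(n, npat, ntip))
  idx_of <- setNames(seq_len(n), sense)
  for (k in seq_len(ntip)) {
    for (p in seq_len(npat)) {
      cd <- codmat[pat_rows[p], k]
      i <- idx_of[cd]
      if (!is.na(i)) {
        tipL[i, p, k] <- 1
      } else if (cd == "---") {
        tipL[, p, k] <- 1
      } else {
        comp <- expand_ambiguous_codon(cd)
        hit <- idx_of[intersect(comp, sense)]
        if (length(hit) == 0L) {
          stop("codon '", cd, "' has no sense-state interpretation")
        }
        tipL[hit, p, k] <- 1
      }
    }
  }
  post <- ape::reorder.phylo(tree, "postorder")
  list(
    tipL = tipL,
    edge = post$edge,
    edge_length = post$edge.length,
    edge_label = branch_labels(post),
    ntip = ntip,
    nnode = post$Nnode,
    npattern = npat,
    nsite = S,
    pattern_weight = as.numeric(tabulate(pat_of_site, npat)),
    pattern_of_site = pat_of_site,
    code = code
  )
}

# linear coefficients of the expected substitution rate of the *unscaled*
# GY94 generator: rate(omega) = a + b * omega for fixed kappa, pi
rate_coefs <- function(kappa, pi, code = genetic_code()) {
  st <- codon_pair_structure(code)
  contrib <- pi[st$i] * pi[st$j] * ifelse(st$is_transition, kappa, 1)
  c(a = sum(contrib[!st$is_nonsyn]), b = sum(contrib[st$is_nonsyn]))
}

# Per-pattern per-class log-likelihoods for a layered model description.
# layers: list, one element per site class, each with
#   $omega      per-edge omega (scalar recycled)
#   $scale      per-edge multiplier applied to branch length (1/rho)
#   $omega2     optional second omega (per-branch episodic mixture)
#   $mixw       weight on omega2 (scalar, 0 = off)
# Returns matrix npattern x nclass.
layer_logliks <- function(td, kappa, pi, layers) {
  nedge <- nrow(td$edge)
  nclass <- length(layers)
  om1 <- matrix(0, nedge, nclass)
  om2 <- matrix(0, nedge, nclass)
  t1 <- matrix(0, nedge, nclass)
  t2 <- matrix(0, nedge, nclass)
  mixw <- numeric(nclass)
  use2 <- logical(nclass)
  for (c in seq_len(nclass)) {
    ly <- layers[[c]]
    om1[, c] <- rep_len(ly$omega, nedge)
    t1[, c] <- td$edge_length * rep_len(ly$scale, nedge)
    if (!is.null(ly$omega2) && !is.null(ly$mixw) && ly$mixw > 0) {
      om2[, c] <- rep_len(ly$omega2, nedge)
      t2[, c] <- t1[, c]
      mixw[c] <- ly$mixw
      use2[c] <- TRUE
    }
  }
  uom <- sort(unique(c(om1, om2[, use2, drop = FALSE])))
  eig <- lapply(uom, function(w) {
    Qr <- build_rate_matrix(kappa, w, pi, code = td$code, scale = FALSE)
    eigen_reversible(Qr$Q, pi)
  })
  map1 <- matrix(match(om1, uom), nedge, nclass)
  map2 <- matrix(0L, nedge, nclass)
  for (c in which(use2)) map2[, c] <- match(om2[, c], uom)
  rootfreq <- matrix(pi, nrow = length(pi), ncol = nclass)
  codon_loglik_cpp(
    td$tipL, td$edge, td$ntip, td$nnode,
    lapply(eig, `[[`, "A"), lapply(eig, `[[`, "B"),
    lapply(eig, `[[`, "lambda"),
    map1, t1, map2, t2, mixw, rootfreq
  )
}

# total log-likelihood from per-pattern class log-likelihoods and weights
mixture_loglik <- function(logL_mat, class_weights, pattern_weight) {
  m <- apply(logL_mat, 1, max)
  lik <- exp(logL_mat - m) %*% class_weights
  sum(pattern_weight * (log(lik) + m))
}

# per-site posterior class membership at fixed weights (NEB)
class_posteriors <- function(logL_mat, class_weights, pattern_of_site) {
  m <- apply(logL_mat, 1, max)
  w <- exp(sweep(logL_mat - m, 2, log(class_weights), `+`))
  post <- w / rowSums(w)
  post[pattern_of_site, , drop = FALSE]
}

# bounded multi-start optimization on transformed (unconstrained) scales.
# objective: function(theta) -> negative log-likelihood
ml_optimize <- function(objective, starts, reltol = 1e-8,
                        max_iter = 500L) {
  neval <- 0L
  wrapped <- function(theta) {
    neval <<- neval + 1L
    val <- tryCatch(objective(theta), error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  best <- NULL
  convs <- logical(0)
  for (s in starts) {
    fit <- stats::nlminb(s, wrapped,
                         control = list(rel.tol = reltol,
                                        iter.max = max_iter))
    convs <- c(convs, fit$convergence == 0L)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  list(par = best$par, objective = best$objective,
       converged = any(convs), n_evaluations = neval)
}

# stick-breaking transform: k-1 unconstrained values -> k-simplex weights,
# floored away from the boundary for identifiability
stick_break <- function(x, floor = 1e-6) {
  k <- length(x) + 1L
  w <- numeric(k)
  rem <- 1
  for (i in seq_len(k - 1L)) {
    f <- stats::plogis(x[i])
    w[i] <- rem * f
    rem <- rem - w[i]
  }
  w[k] <- rem
  w <- pmax(w, floor)
  w / sum(w)
}

stick_break_inv <- function(w) {
  k <- length(w)
  x <- numeric(k - 1L)
  rem <- 1
  for (i in seq_len(k - 1L)) {
    x[i] <- stats::qlogis(min(max(w[i] / rem, 1e-9), 1 - 1e-9))
    rem <- rem - w[i]
  }
  x
}
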