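# Codon model fits: M0 baseline, beta site-class models (M7/M8), M2a_rel,
# clade model C, a RELAX-style selection-intensity test, and simplified
# episodic branch- and site-level tests. All mixture models hold kappa, pi
# and branch lengths fixed at the M0 baseline estimates (standard practice;
# re-fitting branch lengths per model is not attempted).

OMEGA_MAX <- 50
KAPPA_RANGE <- c(0.1, 20)

# bounded smooth transforms
tf_unit <- function(x) stats::plogis(x) # (0,1)
tf_unit_inv <- function(p) stats::qlogis(min(max(p, 1e-8), 1 - 1e-8))
tf_range <- function(x, lo, hi) lo + (hi - lo) * stats::plogis(x)
tf_range_inv <- function(v, lo, hi) {
  tf_unit_inv((min(max(v, lo + 1e-9), hi - 1e-9) - lo) / (hi - lo))
}
tf_logrange <- function(x, lo, hi) lo * (hi / lo)^stats::plogis(x)
tf_logrange_inv <- function(v, lo, hi) {
  tf_unit_inv(log(min(max(v, lo * 1.000001), hi * 0.999999) / lo) /
                log(hi / lo))
}

#' Fit the one-ratio (M0) codon model
#'
#' Estimates kappa, a single omega and a global branch-length scale by
#' maximum likelihood under the GY94 model; the result serves as the
#' baseline (kappa, codon frequencies, branch lengths) that all mixture
#' model fits hold fixed.
#'
#' @param alignment A [codon_alignment()].
#' @param tree [ape::phylo] tree whose leaves match the alignment ids and
#'   whose branch lengths set the relative branch proportions (a global
#'   scale is re-estimated).
#' @param pi_mode Codon frequency scheme, `"F3x4"` (default) or `"equal"`.
#' @param code A [genetic_code()].
#' @return A `codon_fit` with elements `logL`, `mle` (kappa, omega, scale),
#'   `pi`, `tree` (branch lengths rescaled by the fitted scale), `td`
#'   (prepared tip data at the fitted lengths), `converged`,
#'   `n_evaluations`, `identifiable`.
#' @export
fit_m0 <- function(alignment, tree, pi_mode = "F3x4",
                   code = genetic_code()) {
  pi <- codon_frequencies(alignment, mode = pi_mode, code = code)
  td <- prepare_tipdata(alignment, tree, code)
  obj <- function(theta) {
    kappa <- tf_logrange(theta[1], KAPPA_RANGE[1], KAPPA_RANGE[2])
    omega <- tf_range(theta[2], 0, OMEGA_MAX)
    s <- exp(theta[3])
    rc <- rate_coefs(kappa, pi, code)
    rho <- rc[["a"]] + rc[["b"]] * omega
    layers <- list(list(omega = omega, scale = s / rho))
    -mixture_loglik(layer_logliks(td, kappa, pi, layers), 1,
                    td$pattern_weight)
  }
  starts <- list(
    c(tf_logrange_inv(2, 0.1, 20), tf_range_inv(0.4, 0, OMEGA_MAX), 0),
    c(tf_logrange_inv(1, 0.1, 20), tf_range_inv(1, 0, OMEGA_MAX), 0),
    c(tf_logrange_inv(4, 0.1, 20), tf_range_inv(0.1, 0, OMEGA_MAX),
      log(0.5))
  )
  opt <- ml_optimize(obj, starts)
  kappa <- tf_logrange(opt$par[1], 0.1, 20)
  omega <- tf_range(opt$par[2], 0, OMEGA_MAX)
  s <- exp(opt$par[3])
  tree_scaled <- tree
  tree_scaled$edge.length <- tree$edge.length * s
  td$edge_length <- td$edge_length * s
  structure(list(
    family = "M0",
    logL = -opt$objective,
    mle = list(kappa = kappa, omega = omega, scale = s),
    pi = pi,
    tree = tree_scaled,
    td = td,
    converged = opt$converged,
    n_evaluations = opt$n_evaluations,
    identifiable = s > 1e-6
  ), class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon model fit [", x$family, "]  logL = ",
      formatC(x$logL, digits = 6, format = "f"), "\n", sep = "")
  mles <- unlist(x$mle)
  cat(paste0("  ", names(mles), " = ",
             formatC(mles, digits = 4, format = "g"), collapse = "\n"),
      "\n")
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

# a baseline bundle for mixture fits: either a fitted M0 or components
as_baseline <- function(alignment, tree, baseline = NULL,
                        code = genetic_code(), pi_mode = "F3x4") {
  if (is.null(baseline)) baseline <- fit_m0(alignment, tree,
                                            pi_mode = pi_mode, code = code)
  baseline
}

# equal-probability beta bin representatives (median quantiles)
beta_bin_omegas <- function(p, q, k = 10L) {
  stats::qbeta((2 * seq_len(k) - 1) / (2 * k), p, q)
}

#' Likelihood-ratio test between nested fits
#'
#' @param null_fit,alt_fit `codon_fit` objects on the same data.
#' @param df Degrees of freedom for a plain chi-square reference.
#' @param mixture Optional mixture reference: list with `weights` and `dfs`
#'   (df 0 means a point mass at 0), e.g.
#'   `list(weights = c(.5, .5), dfs = c(0, 1))`.
#' @return List with `statistic` (`max(0, 2 dlogL)`), `df`, `p`.
#' @export
lrt <- function(null_fit, alt_fit, df = NULL, mixture = NULL) {
  stat <- max(0, 2 * (alt_fit$logL - null_fit$logL))
  if (is.null(mixture)) {
    if (is.null(df) || df <= 0) stop("df must be positive (or give mixture)")
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  } else {
    p <- sum(mixture$weights * vapply(mixture$dfs, function(d) {
      if (d == 0) as.numeric(stat <= 0)
      else stats::pchisq(stat, df = d, lower.tail = FALSE)
    }, numeric(1)))
    df <- NA_real_
  }
  list(statistic = stat, df = df, p = min(p, 1))
}

#' Fit the M7 (beta) and M8 (beta + spike) site models and test M8 vs M7
#'
#' M7 draws site omega from a 10-bin discretized Beta(p, q) on (0, 1); M8
#' adds a spike class with omega >= 1 and weight `1 - p0`. The LRT uses
#' chi-square with 2 df. Naive empirical-Bayes posteriors of the spike
#' class flag positively selected sites (tag "M").
#'
#' @inheritParams fit_m0
#' @param baseline Optional [fit_m0()] result to reuse.
#' @param n_categories Beta discretization bins (default 10).
#' @param posterior_cutoff NEB flag threshold (default 0.95).
#' @return List with `fit_m7`, `fit_m8`, `lrt`, and `sites` (data frame:
#'   `site`, `posterior`, `method` = "M", `flagged`).
#' @export
site_test_m7m8 <- function(alignment, tree, baseline = NULL,
                           n_categories = 10L, posterior_cutoff = 0.95,
                           code = genetic_code()) {
  bl <- as_baseline(alignment, tree, baseline, code)
  td <- bl$td
  kappa <- bl$mle$kappa
  pi <- bl$pi
  rc <- rate_coefs(kappa, pi, code)
  K <- n_categories

  m7_obj <- function(theta) {
    p <- tf_logrange(theta[1], 0.005, 100)
    q <- tf_logrange(theta[2], 0.005, 100)
    om <- beta_bin_omegas(p, q, K)
    rho <- rc[["a"]] + rc[["b"]] * mean(om)
    layers <- lapply(om, function(w) list(omega = w, scale = 1 / rho))
    -mixture_loglik(layer_logliks(td, kappa, pi, layers),
                    rep(1 / K, K), td$pattern_weight)
  }
  st7 <- list(
    c(tf_logrange_inv(0.5, 0.005, 100), tf_logrange_inv(1.5, 0.005, 100)),
    c(tf_logrange_inv(1, 0.005, 100), tf_logrange_inv(1, 0.005, 100)),
    c(tf_logrange_inv(0.2, 0.005, 100), tf_logrange_inv(2, 0.005, 100))
  )
  o7 <- ml_optimize(m7_obj, st7)
  p7 <- tf_logrange(o7$par[1], 0.005, 100)
  q7 <- tf_logrange(o7$par[2], 0.005, 100)
  fit7 <- structure(list(
    family = "M7", logL = -o7$objective,
    mle = list(p = p7, q = q7), pi = pi, tree = bl$tree,
    converged = o7$converged, n_evaluations = o7$n_evaluations
  ), class = "codon_fit")

  m8_parts <- function(theta) {
    list(p = tf_logrange(theta[1], 0.005, 100),
         q = tf_logrange(theta[2], 0.005, 100),
         p0 = tf_unit(theta[3]),
         omega_s = tf_range(theta[4], 1, OMEGA_MAX))
  }
  m8_layers <- function(pp) {
    om <- c(beta_bin_omegas(pp$p, pp$q, K), pp$omega_s)
    w <- c(rep(pp$p0 / K, K), 1 - pp$p0)
    rho <- rc[["a"]] + rc[["b"]] * sum(w * om)
    list(layers = lapply(om, function(x) list(omega = x, scale = 1 / rho)),
         weights = w, omegas = om)
  }
  m8_obj <- function(theta) {
    pp <- m8_parts(theta)
    ly <- m8_layers(pp)
    -mixture_loglik(layer_logliks(td, kappa, pi, ly$layers), ly$weights,
                    td$pattern_weight)
  }
  st8 <- list(
    c(o7$par[1], o7$par[2], tf_unit_inv(0.95), tf_range_inv(2, 1, OMEGA_MAX)),
    c(o7$par[1], o7$par[2], tf_unit_inv(0.99),
      tf_range_inv(1.001, 1, OMEGA_MAX)),
    c(tf_logrange_inv(0.5, 0.005, 100), tf_logrange_inv(1.5, 0.005, 100),
      tf_unit_inv(0.8), tf_range_inv(4, 1, OMEGA_MAX))
  )
  o8 <- ml_optimize(m8_obj, st8)
  # enforce logL(M8) >= logL(M7): the M7 MLE lies on the M8 boundary
  if (-o8$objective < -o7$objective) {
    o8$objective <- o7$objective
    o8$par <- c(o7$par[1], o7$par[2], tf_unit_inv(1 - 1e-8),
                tf_range_inv(1, 1, OMEGA_MAX))
  }
  pp <- m8_parts(o8$par)
  fit8 <- structure(list(
    family = "M8", logL = -o8$objective,
    mle = list(p = pp$p, q = pp$q, p0 = pp$p0, omega_s = pp$omega_s),
    pi = pi, tree = bl$tree,
    converged = o8$converged, n_evaluations = o8$n_evaluations
  ), class = "codon_fit")

  ly <- m8_layers(m8_parts(o8$par))
  logL_mat <- layer_logliks(td, kappa, pi, ly$layers)
  post <- class_posteriors(logL_mat, ly$weights, td$pattern_of_site)
  spike <- post[, K + 1L]
  sites <- data.frame(
    site = seq_len(td$nsite),
    posterior = spike,
    method = "M",
    flagged = spike > posterior_cutoff,
    stringsAsFactors = FALSE
  )
  list(fit_m7 = fit7, fit_m8 = fit8,
       lrt = lrt(fit7, fit8, df = 2),
       sites = sites)
}

# single-class fit with one free omega per branch partition (kappa and
# branch lengths fixed); used only to seed clade-model starts
partition_omegas <- function(td, kappa, pi, edge_part, npart, rc) {
  obj <- function(theta) {
    om <- tf_range(theta, 0, OMEGA_MAX)
    rho <- rc[["a"]] + rc[["b"]] * om
    layers <- list(list(omega = om[edge_part],
                        scale = 1 / rho[edge_part]))
    -mixture_loglik(layer_logliks(td, kappa, pi, layers), 1,
                    td$pattern_weight)
  }
  o <- ml_optimize(obj, list(rep(tf_range_inv(0.3, 0, OMEGA_MAX), npart)),
                   max_iter = 200L)
  tf_range(o$par, 0, OMEGA_MAX)
}

# shared machinery for the three-class models (M2a_rel / CmC / RELAX).
# Builds layers for given per-partition class omegas with per-partition
# mixture-rate scaling. omega_by_part: 3 x npart matrix; edge_part: integer
# partition index per edge.
three_class_layers <- function(omega_by_part, weights, edge_part, rc) {
  npart <- ncol(omega_by_part)
  rho <- vapply(seq_len(npart), function(p) {
    rc[["a"]] + rc[["b"]] * sum(weights * omega_by_part[, p])
  }, numeric(1))
  lapply(1:3, function(cl) {
    list(omega = omega_by_part[cl, edge_part],
         scale = 1 / rho[edge_part])
  })
}

#' Fit the M2a_rel model (null of clade model C)
#'
#' Three site classes shared by all branches: omega0 <= 1, omega1 = 1, and a
#' free omega2, with free proportions.
#'
#' @inheritParams site_test_m7m8
#' @return A `codon_fit` with `mle` elements `omega0`, `omega2`, `p0`, `p1`,
#'   `p2`.
#' @export
fit_m2a_rel <- function(alignment, tree, baseline = NULL,
                        code = genetic_code()) {
  bl <- as_baseline(alignment, tree, baseline, code)
  td <- bl$td
  kappa <- bl$mle$kappa
  pi <- bl$pi
  rc <- rate_coefs(kappa, pi, code)
  edge_part <- rep(1L, nrow(td$edge))
  obj <- function(theta) {
    om <- matrix(c(tf_unit(theta[1]), 1, tf_range(theta[2], 0, OMEGA_MAX)),
                 ncol = 1)
    w <- stick_break(theta[3:4])
    layers <- three_class_layers(om, w, edge_part, rc)
    -mixture_loglik(layer_logliks(td, kappa, pi, layers), w,
                    td$pattern_weight)
  }
  om_m0 <- bl$mle$omega
  starts <- list(
    # data-informed: split the M0 omega into a purifying and a free class
    c(tf_unit_inv(min(0.2, om_m0 / 2)),
      tf_range_inv(max(1.2 * om_m0, 0.3), 0, OMEGA_MAX),
      stick_break_inv(c(0.55, 0.1, 0.35))),
    c(tf_unit_inv(0.05), tf_range_inv(0.5, 0, OMEGA_MAX),
      stick_break_inv(c(0.6, 0.1, 0.3))),
    c(tf_unit_inv(0.2), tf_range_inv(1.5, 0, OMEGA_MAX),
      stick_break_inv(c(0.4, 0.3, 0.3))),
    c(tf_unit_inv(0.02), tf_range_inv(om_m0, 0, OMEGA_MAX),
      stick_break_inv(c(0.45, 0.15, 0.4)))
  )
  opt <- ml_optimize(obj, starts)
  w <- stick_break(opt$par[3:4])
  structure(list(
    family = "M2a_rel", logL = -opt$objective,
    mle = list(omega0 = tf_unit(opt$par[1]), omega1 = 1,
               omega2 = tf_range(opt$par[2], 0, OMEGA_MAX),
               p0 = w[1], p1 = w[2], p2 = w[3]),
    par = opt$par, pi = pi, tree = bl$tree,
    converged = opt$converged, n_evaluations = opt$n_evaluations
  ), class = "codon_fit")
}

#' Fit clade model C and test it against M2a_rel
#'
#' Site classes 0 (omega0 <= 1) and 1 (omega1 = 1) are shared by all
#' branches; the third class omega2 is estimated separately for every branch
#' partition (the labeled clades plus, by default, the unlabeled
#' background). The null model is [fit_m2a_rel()] (one shared omega2); the
#' LRT has `n_partitions - 1` degrees of freedom.
#'
#' @inheritParams site_test_m7m8
#' @param tree A tree labeled with [label_clades()] carrying at least two
#'   partitions.
#' @return List with `fit` (CmC; `mle` includes `omega2` as a named vector
#'   per partition), `fit_null`, `lrt`.
#' @export
fit_clade_model_c <- function(alignment, tree, baseline = NULL,
                              code = genetic_code()) {
  labs <- branch_labels(tree)
  parts <- sort(unique(labs))
  if (length(parts) < 2L) {
    stop("clade model C needs >= 2 branch partitions; label the tree first")
  }
  bl <- as_baseline(alignment, tree, baseline, code)
  null_fit <- fit_m2a_rel(alignment, tree, baseline = bl, code = code)
  td <- bl$td
  kappa <- bl$mle$kappa
  pi <- bl$pi
  rc <- rate_coefs(kappa, pi, code)
  edge_part <- match(td$edge_label, parts)
  npart <- length(parts)
  obj <- function(theta) {
    om2 <- tf_range(theta[3 + seq_len(npart)], 0, OMEGA_MAX)
    om <- rbind(rep(tf_unit(theta[1]), npart), rep(1, npart), om2)
    w <- stick_break(theta[2:3])
    layers <- three_class_layers(om, w, edge_part, rc)
    -mixture_loglik(layer_logliks(td, kappa, pi, layers), w,
                    td$pattern_weight)
  }
  np <- null_fit$par
  warm <- c(np[1], np[3], np[4],
            rep(tf_range_inv(null_fit$mle$omega2, 0, OMEGA_MAX), npart))
  # cheap per-partition one-ratio fit to seed the divergent class-2 omegas
  om_part <- partition_omegas(td, bl$mle$kappa, pi, edge_part, npart, rc)
  om2_seed <- null_fit$mle$omega2 * om_part / mean(om_part)
  warm2 <- c(np[1], np[3], np[4],
             vapply(om2_seed, tf_range_inv, numeric(1), 0, OMEGA_MAX))
  starts <- list(
    warm,
    warm2,
    c(tf_unit_inv(0.05), stick_break_inv(c(0.55, 0.1, 0.35)),
      vapply(pmax(om_part, 0.05), tf_range_inv, numeric(1), 0, OMEGA_MAX))
  )
  opt <- ml_optimize(obj, starts)
  if (-opt$objective < null_fit$logL) {
    opt$objective <- -null_fit$logL
    opt$par <- warm
  }
  w <- stick_break(opt$par[2:3])
  om2 <- tf_range(opt$par[3 + seq_len(npart)], 0, OMEGA_MAX)
  names(om2) <- parts
  fit <- structure(list(
    family = "CmC", logL = -opt$objective,
    mle = list(omega0 = tf_unit(opt$par[1]), omega1 = 1, omega2 = om2,
               p0 = w[1], p1 = w[2], p2 = w[3]),
    partitions = parts, pi = pi, tree = bl$tree,
    converged = opt$converged, n_evaluations = opt$n_evaluations
  ), class = "codon_fit")
  list(fit = fit, fit_null = null_fit,
       lrt = lrt(null_fit, fit, df = npart - 1L))
}

#' RELAX-style test of selection intensity
#'
#' Reference branches carry three omega classes (omega0 <= 1, 1, omega2
#' free); test branches carry the same classes raised to the power k. k > 1
#' indicates intensified selection on the test branches, k < 1 relaxed; the
#' null fixes k = 1 (LRT df 1). Branches labeled neither `"Test"` nor
#' `"Reference"` are treated as reference. Synonymous-rate variation across
#' sites is not modeled.
#'
#' @inheritParams site_test_m7m8
#' @param tree Tree labeled (via [label_clades()]) with `"Test"` and
#'   `"Reference"` partitions.
#' @return List with `fit` (alternative; `mle` has `k`), `fit_null`, `lrt`,
#'   and `mean_omega` (named: Test, Reference) at the alternative MLE.
#' @export
fit_relax <- function(alignment, tree, baseline = NULL,
                      code = genetic_code()) {
  labs <- branch_labels(tree)
  if (!("Test" %in% labs)) stop("tree carries no 'Test' branches")
  bl <- as_baseline(alignment, tree, baseline, code)
  td <- bl$td
  kappa <- bl$mle$kappa
  pi <- bl$pi
  rc <- rate_coefs(kappa, pi, code)
  edge_part <- ifelse(td$edge_label == "Test", 2L, 1L) # 1 = Reference
  relax_om <- function(theta, k) {
    om_ref <- c(tf_unit(theta[1]), 1, tf_range(theta[2], 0, OMEGA_MAX))
    om_test <- pmin(om_ref^k, OMEGA_MAX)
    cbind(om_ref, om_test)
  }
  make_obj <- function(free_k) {
    function(theta) {
      k <- if (free_k) tf_logrange(theta[5], 0.02, 50) else 1
      om <- relax_om(theta, k)
      w <- stick_break(theta[3:4])
      layers <- three_class_layers(om, w, edge_part, rc)
      -mixture_loglik(layer_logliks(td, kappa, pi, layers), w,
                      td$pattern_weight)
    }
  }
  om_m0 <- bl$mle$omega
  base_starts <- list(
    c(tf_unit_inv(min(0.2, om_m0 / 2)),
      tf_range_inv(max(1.2 * om_m0, 0.3), 0, OMEGA_MAX),
      stick_break_inv(c(0.55, 0.1, 0.35))),
    c(tf_unit_inv(0.2), tf_range_inv(1.5, 0, OMEGA_MAX),
      stick_break_inv(c(0.4, 0.3, 0.3))),
    c(tf_unit_inv(0.01), tf_range_inv(0.3, 0, OMEGA_MAX),
      stick_break_inv(c(0.7, 0.05, 0.25)))
  )
  o_null <- ml_optimize(make_obj(FALSE), base_starts)
  w_null <- stick_break(o_null$par[3:4])
  fit_null <- structure(list(
    family = "RELAX_null", logL = -o_null$objective,
    mle = list(omega0 = tf_unit(o_null$par[1]), omega1 = 1,
               omega2 = tf_range(o_null$par[2], 0, OMEGA_MAX),
               p0 = w_null[1], p1 = w_null[2], p2 = w_null[3], k = 1),
    pi = pi, tree = bl$tree,
    converged = o_null$converged, n_evaluations = o_null$n_evaluations
  ), class = "codon_fit")
  alt_starts <- list(
    c(o_null$par, tf_logrange_inv(1, 0.02, 50)),
    c(o_null$par, tf_logrange_inv(3, 0.02, 50)),
    c(o_null$par, tf_logrange_inv(0.33, 0.02, 50))
  )
  o_alt <- ml_optimize(make_obj(TRUE), alt_starts)
  if (-o_alt$objective < fit_null$logL) {
    o_alt$objective <- o_null$objective
    o_alt$par <- c(o_null$par, tf_logrange_inv(1, 0.02, 50))
  }
  k_hat <- tf_logrange(o_alt$par[5], 0.02, 50)
  w <- stick_break(o_alt$par[3:4])
  om <- relax_om(o_alt$par, k_hat)
  mean_omega <- c(Test = sum(w * om[, 2]), Reference = sum(w * om[, 1]))
  fit_alt <- structure(list(
    family = "RELAX", logL = -o_alt$objective,
    mle = list(omega0 = tf_unit(o_alt$par[1]), omega1 = 1,
               omega2 = tf_range(o_alt$par[2], 0, OMEGA_MAX),
               p0 = w[1], p1 = w[2], p2 = w[3], k = k_hat),
    pi = pi, tree = bl$tree,
    converged = o_alt$converged, n_evaluations = o_alt$n_evaluations
  ), class = "codon_fit")
  list(fit = fit_alt, fit_null = fit_null,
       lrt = lrt(fit_null, fit_alt, df = 1),
       mean_omega = mean_omega)
}
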