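# Simplified episodic selection tests (fixed two-class variants of the
# adaptive branch-site and per-site branch-mixture approaches) and the
# grid empirical-Bayes site test. All use the M0 baseline for kappa, codon
# frequencies and branch lengths; rate matrices are normalized by the
# baseline omega's expected rate so branch lengths keep their M0 meaning.

baseline_scale <- function(bl, code) {
  rc <- rate_coefs(bl$mle$kappa, bl$pi, code)
  1 / (rc[["a"]] + rc[["b"]] * bl$mle$omega)
}

#' Episodic positive-selection test on one branch
#'
#' The focal branch carries two site classes (omega- <= 1 with weight p;
#' omega+ >= 1 with weight 1 - p) while all other branches share a single
#' free background omega. The null constrains omega+ = 1; the LRT reference
#' is the boundary mixture `0.5 chi2_0 + 0.5 chi2_1`.
#'
#' @inheritParams site_test_m7m8
#' @param focal_child Child-node id of the focal branch (a row of
#'   `tree$edge`); tip ids 1..ntip correspond to `tree$tip.label`.
#' @return List with `fit`, `fit_null`, `lrt` (boundary-mixture p), and
#'   `focal_child`.
#' @export
branch_test_episodic <- function(alignment, tree, focal_child,
                                 baseline = NULL, code = genetic_code()) {
  bl <- as_baseline(alignment, tree, baseline, code)
  td <- bl$td
  e_focal <- which(td$edge[, 2] == focal_child)
  if (length(e_focal) != 1L) stop("focal branch not found: ", focal_child)
  if (td$edge_length[e_focal] <= 0) {
    warning("zero-length focal branch; test has no power (p = 1)")
    nullres <- list(statistic = 0, df = NA_real_, p = 1)
    return(list(fit = NULL, fit_null = NULL, lrt = nullres,
                focal_child = focal_child))
  }
  kappa <- bl$mle$kappa
  pi <- bl$pi
  sc <- baseline_scale(bl, code)
  nedge <- nrow(td$edge)
  make_obj <- function(free_plus) {
    function(theta) {
      om_minus <- tf_unit(theta[1])
      om_plus <- if (free_plus) tf_range(theta[4], 1, OMEGA_MAX) else 1
      p <- tf_unit(theta[2])
      om_bg <- tf_range(theta[3], 0, OMEGA_MAX)
      o1 <- rep(om_bg, nedge); o1[e_focal] <- om_minus
      o2 <- rep(om_bg, nedge); o2[e_focal] <- om_plus
      layers <- list(list(omega = o1, scale = sc),
                     list(omega = o2, scale = sc))
      -mixture_loglik(layer_logliks(td, kappa, pi, layers), c(p, 1 - p),
                      td$pattern_weight)
    }
  }
  om0 <- min(bl$mle$omega, 0.9)
  st_null <- list(
    c(tf_unit_inv(om0), tf_unit_inv(0.8),
      tf_range_inv(bl$mle$omega, 0, OMEGA_MAX)),
    c(tf_unit_inv(0.1), tf_unit_inv(0.5),
      tf_range_inv(0.5, 0, OMEGA_MAX))
  )
  o_null <- ml_optimize(make_obj(FALSE), st_null)
  st_alt <- list(
    c(o_null$par, tf_range_inv(1.5, 1, OMEGA_MAX)),
    c(o_null$par, tf_range_inv(6, 1, OMEGA_MAX))
  )
  o_alt <- ml_optimize(make_obj(TRUE), st_alt)
  if (o_alt$objective > o_null$objective) o_alt$objective <- o_null$objective
  fit_null <- structure(list(
    family = "branch_episodic_null", logL = -o_null$objective,
    mle = list(omega_minus = tf_unit(o_null$par[1]),
               p_minus = tf_unit(o_null$par[2]),
               omega_bg = tf_range(o_null$par[3], 0, OMEGA_MAX)),
    pi = pi, tree = bl$tree, converged = o_null$converged,
    n_evaluations = o_null$n_evaluations
  ), class = "codon_fit")
  fit_alt <- structure(list(
    family = "branch_episodic", logL = -o_alt$objective,
    mle = list(omega_minus = tf_unit(o_alt$par[1]),
               p_minus = tf_unit(o_alt$par[2]),
               omega_bg = tf_range(o_alt$par[3], 0, OMEGA_MAX),
               omega_plus = tf_range(o_alt$par[4], 1, OMEGA_MAX)),
    pi = pi, tree = bl$tree, converged = o_alt$converged,
    n_evaluations = o_alt$n_evaluations
  ), class = "codon_fit")
  list(fit = fit_alt, fit_null = fit_null,
       lrt = lrt(fit_null, fit_alt,
                 mixture = list(weights = c(0.5, 0.5), dfs = c(0, 1))),
       focal_child = focal_child)
}

#' Branch sweep for episodic positive selection
#'
#' Applies [branch_test_episodic()] to every branch and reports uncorrected
#' and Holm-corrected p values.
#'
#' @inheritParams branch_test_episodic
#' @param correction Multiple-testing method for [stats::p.adjust()]
#'   (default `"holm"`).
#' @return Data frame with one row per branch: `child`, `parent`, `length`,
#'   `is_external`, `omega_plus`, `p`, `p_corrected`, `selected`
#'   (uncorrected p < 0.05), `selected_corrected`.
#' @export
branch_sweep_episodic <- function(alignment, tree, baseline = NULL,
                                  correction = "holm",
                                  code = genetic_code()) {
  bl <- as_baseline(alignment, tree, baseline, code)
  inv <- branch_inventory(tree)
  res <- lapply(inv$child, function(ch) {
    r <- branch_test_episodic(alignment, tree, ch, baseline = bl,
                              code = code)
    data.frame(child = ch,
               omega_plus = if (is.null(r$fit)) NA_real_
                            else r$fit$mle$omega_plus,
               p = r$lrt$p)
  })
  out <- do.call(rbind, res)
  out <- cbind(inv[, c("parent", "length", "is_external")], out)
  out$p_corrected <- stats::p.adjust(out$p, method = correction)
  out$selected <- out$p < 0.05
  out$selected_corrected <- out$p_corrected < 0.05
  out[, c("child", "parent", "length", "is_external", "omega_plus",
          "p", "p_corrected", "selected", "selected_corrected")]
}

#' Per-site episodic positive-selection test
#'
#' For each codon site, every branch independently draws one of two rate
#' classes (omega- <= 1 with weight p-; omega+ free), so the per-branch
#' transition matrix is the weight-mixed pair. The alternative estimates
#' (omega-, omega+, p-) per site; the null constrains omega+ <= 1. Per-site
#' p values come from a chi-square reference with `df` degrees of freedom
#' (default 2, conservative); sites are flagged at p < 0.05 (tag "E").
#'
#' @inheritParams site_test_m7m8
#' @param df Degrees of freedom of the per-site LRT reference.
#' @param p_cutoff Flagging threshold (default 0.05).
#' @return Data frame with `site`, `omega_plus`, `p_plus`, `statistic`,
#'   `p`, `method` = "E", `flagged`; all-gap sites carry NA and a note.
#' @export
site_test_episodic <- function(alignment, tree, baseline = NULL, df = 2,
                               p_cutoff = 0.05, code = genetic_code()) {
  bl <- as_baseline(alignment, tree, baseline, code)
  td <- bl$td
  kappa <- bl$mle$kappa
  pi <- bl$pi
  sc <- baseline_scale(bl, code)
  out <- data.frame(site = seq_len(td$nsite), omega_plus = NA_real_,
                    p_plus = NA_real_, statistic = NA_real_, p = NA_real_,
                    method = "E", flagged = FALSE,
                    stringsAsFactors = FALSE)
  done <- rep(FALSE, td$npattern)
  pat_res <- vector("list", td$npattern)
  for (s in seq_len(td$nsite)) {
    pat <- td$pattern_of_site[s]
    if (!done[pat]) {
      done[pat] <- TRUE
      pat_res[[pat]] <- site_episodic_one(td, pat, kappa, pi, sc, df)
    }
    r <- pat_res[[pat]]
    if (is.null(r)) next # all-gap site: skipped
    out$omega_plus[s] <- r$omega_plus
    out$p_plus[s] <- r$p_plus
    out$statistic[s] <- r$statistic
    out$p[s] <- r$p
    out$flagged[s] <- is.finite(r$p) && r$p < p_cutoff
  }
  out
}

site_episodic_one <- function(td, pat, kappa, pi, sc, df) {
  tds <- td
  tds$tipL <- td$tipL[, pat, , drop = FALSE]
  tds$npattern <- 1L
  tds$pattern_weight <- 1
  if (all(apply(tds$tipL[, 1, ], 2, function(v) all(v == 1)))) {
    return(NULL) # no data at this site
  }
  make_obj <- function(plus_free) {
    function(theta) {
      om_minus <- tf_unit(theta[1])
      p_minus <- tf_unit(theta[2])
      om_plus <- if (plus_free) tf_range(theta[3], 0, OMEGA_MAX)
                 else tf_unit(theta[3])
      layers <- list(list(omega = om_minus, scale = sc,
                          omega2 = om_plus, mixw = 1 - p_minus))
      -mixture_loglik(layer_logliks(tds, kappa, pi, layers), 1, 1)
    }
  }
  st_null <- list(c(tf_unit_inv(0.2), tf_unit_inv(0.8), tf_unit_inv(0.9)),
                  c(tf_unit_inv(0.05), tf_unit_inv(0.5), tf_unit_inv(0.5)))
  o_null <- ml_optimize(make_obj(FALSE), st_null, max_iter = 200L)
  st_alt <- list(c(o_null$par[1:2], tf_range_inv(2, 0, OMEGA_MAX)),
                 c(o_null$par[1:2], tf_range_inv(8, 0, OMEGA_MAX)))
  o_alt <- ml_optimize(make_obj(TRUE), st_alt, max_iter = 200L)
  if (o_alt$objective > o_null$objective) o_alt$objective <- o_null$objective
  stat <- max(0, 2 * (o_null$objective - o_alt$objective))
  list(
    omega_plus = tf_range(o_alt$par[3], 0, OMEGA_MAX),
    p_plus = 1 - tf_unit(o_alt$par[2]),
    statistic = stat,
    p = if (stat <= 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  )
}

#' Grid empirical-Bayes site test for pervasive selection
#'
#' Site likelihoods are evaluated on a fixed omega grid (default 20 points:
#' 0, then log-spaced 0.05-10, plus 1); grid weights are estimated by EM on
#' the marginal likelihood with a symmetric Dirichlet(0.5) regularizer, and
#' each site reports the posterior probability that its omega exceeds 1
#' (tag "F"; flagged at > 0.9 by default).
#'
#' @inheritParams site_test_m7m8
#' @param grid Omega grid (default as above).
#' @param alpha Dirichlet concentration of the weight regularizer.
#' @param posterior_cutoff Flagging threshold.
#' @return List with `sites` (data frame: `site`, `posterior`, `method` =
#'   "F", `flagged`), `grid`, `weights`, `objective_trace`.
#' @export
site_test_grid_eb <- function(alignment, tree, baseline = NULL,
                              grid = NULL, alpha = 0.5,
                              posterior_cutoff = 0.9,
                              code = genetic_code()) {
  bl <- as_baseline(alignment, tree, baseline, code)
  td <- bl$td
  kappa <- bl$mle$kappa
  pi <- bl$pi
  rc <- rate_coefs(kappa, pi, code)
  if (is.null(grid)) {
    grid <- sort(unique(c(0, 1, exp(seq(log(0.05), log(10),
                                        length.out = 18)))))
  }
  G <- length(grid)
  layers <- lapply(grid, function(w) {
    list(omega = w, scale = 1 / (rc[["a"]] + rc[["b"]] * w))
  })
  logL <- layer_logliks(td, kappa, pi, layers) # npattern x G
  m <- apply(logL, 1, max)
  L <- exp(logL - m) # scaled likelihoods; scale cancels in EM and posterior
  nw <- td$pattern_weight
  w <- rep(1 / G, G)
  objective <- function(w) {
    sum(nw * log(L %*% w)) + sum((alpha - 1) * log(w))
  }
  trace <- objective(w)
  for (it in seq_len(500L)) {
    denom <- as.vector(L %*% w)
    resp <- L * rep(w, each = nrow(L)) / denom
    Ng <- colSums(resp * nw)
    w_new <- Ng + (alpha - 1)
    w_new <- pmax(w_new, 1e-8)
    w_new <- w_new / sum(w_new)
    obj_new <- objective(w_new)
    if (obj_new < utils::tail(trace, 1) - 1e-6) {
      stop("EM objective decreased; this indicates a bug")
    }
    trace <- c(trace, obj_new)
    delta <- obj_new - trace[length(trace) - 1L]
    w <- w_new
    if (abs(delta) < 1e-8) break
  }
  sel <- grid > 1
  post_pat <- as.vector((L[, sel, drop = FALSE] %*% w[sel]) /
                          (L %*% w))
  post <- post_pat[td$pattern_of_site]
  sites <- data.frame(site = seq_len(td$nsite), posterior = post,
                      method = "F", flagged = post > posterior_cutoff,
                      stringsAsFactors = FALSE)
  list(sites = sites, grid = grid, weights = w, objective_trace = trace)
}

#' Naive empirical-Bayes site-class posteriors for a mixture fit
#'
#' Evaluates, at the fit's maximum-likelihood estimates, the posterior
#' probability of each site class for every alignment site.
#'
#' @param fit A mixture `codon_fit` (M8, M2a_rel, CmC or RELAX result).
#' @param alignment,tree Data the fit was obtained on.
#' @param baseline The [fit_m0()] baseline used for the fit.
#' @param code A [genetic_code()].
#' @return Matrix `n_sites x n_classes` of posteriors (rows sum to 1).
#' @export
neb_posteriors <- function(fit, alignment, tree, baseline = NULL,
                           code = genetic_code()) {
  bl <- as_baseline(alignment, tree, baseline, code)
  td <- bl$td
  kappa <- bl$mle$kappa
  pi <- bl$pi
  rc <- rate_coefs(kappa, pi, code)
  m <- fit$mle
  if (fit$family == "M8") {
    om <- c(beta_bin_omegas(m$p, m$q, 10L), m$omega_s)
    wts <- c(rep(m$p0 / 10, 10), 1 - m$p0)
    rho <- rc[["a"]] + rc[["b"]] * sum(wts * om)
    layers <- lapply(om, function(x) list(omega = x, scale = 1 / rho))
  } else if (fit$family %in% c("M2a_rel", "CmC")) {
    parts <- if (is.null(fit$partitions)) "background" else fit$partitions
    om2 <- rep_len(m$omega2, length(parts))
    om <- rbind(rep(m$omega0, length(parts)), 1, om2)
    wts <- c(m$p0, m$p1, m$p2)
    edge_part <- match(td$edge_label, parts)
    edge_part[is.na(edge_part)] <- 1L
    layers <- three_class_layers(om, wts, edge_part, rc)
  } else if (fit$family == "M0") {
    return(matrix(1, nrow = td$nsite, ncol = 1))
  } else {
    stop("NEB posteriors not defined for family ", fit$family)
  }
  logL <- layer_logliks(td, kappa, pi, layers)
  class_posteriors(logL, wts, td$pattern_of_site)
}
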