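#' Codon stationary frequencies
#'
#' Computes stationary frequencies over the sense codons, either equal or by
#' the F3x4 scheme (product of position-specific nucleotide frequencies,
#' restricted to sense codons and renormalized). F3x4 adds 0.5 pseudo-counts
#' per nucleotide per codon position.
#'
#' @param alignment A [codon_alignment()] (ignored for `mode = "equal"`).
#' @param mode `"F3x4"` or `"equal"`.
#' @param code A [genetic_code()].
#' @return Named numeric vector over `code$sense_codons`, summing to 1.
#' @export
codon_frequencies <- function(alignment = NULL, mode = c("F3x4", "equal"),
                              code = genetic_code()) {
  mode <- match.arg(mode)
  sense <- code$sense_codons
  if (mode == "equal") {
    pi <- rep(1 / length(sense), length(sense))
    names(pi) <- sense
    return(pi)
  }
  stopifnot(!is.null(alignment))
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0.5, nrow = 3, ncol = 4,
                   dimnames = list(NULL, bases))
  for (row in alignment$residues) {
    chars <- strsplit(toupper(row), "")[[1]]
    pos <- rep_len(1:3, length(chars))
    for (b in bases) {
      hit <- chars == b
      counts[, b] <- counts[, b] + tabulate(pos[hit], 3)
    }
  }
  pfreq <- counts / rowSums(counts)
  pi <- vapply(sense, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    pfreq[1, ch[1]] * pfreq[2, ch[2]] * pfreq[3, ch[3]]
  }, numeric(1))
  pi / sum(pi)
}

#' Build a GY94 codon rate matrix
#'
#' Entries between codons differing at exactly one position are
#' `pi_j * {1, kappa, omega, kappa * omega}` for synonymous transversions,
#' synonymous transitions, nonsynonymous transversions and nonsynonymous
#' transitions; all other off-diagonals are 0 and the diagonal makes rows
#' sum to 0. By default the matrix is rescaled so the expected substitution
#' rate at stationarity is 1 per unit branch length.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Stationary frequencies over sense codons (sum 1).
#' @param code A [genetic_code()].
#' @param scale Rescale to unit expected rate (default TRUE). Set FALSE to
#'   obtain the raw generator, e.g. when a shared mixture-level scale is
#'   applied externally.
#' @return List with `Q` (n_sense x n_sense), `pi`, and `rate` (the expected
#'   substitution rate of the unscaled generator).
#' @export
build_rate_matrix <- function(kappa, omega, pi, code = genetic_code(),
                              scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0)
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < 0)) {
    stop("pi must be non-negative and sum to 1")
  }
  st <- codon_pair_structure(code)
  n <- length(code$sense_codons)
  Q <- matrix(0, n, n, dimnames = list(code$sense_codons,
                                       code$sense_codons))
  rate_fac <- ifelse(st$is_transition, kappa, 1) *
    ifelse(st$is_nonsyn, omega, 1)
  Q[st$pair_index] <- rate_fac * pi[st$j]
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (scale) {
    if (rate <= 0) stop("degenerate rate matrix (expected rate 0)")
    Q <- Q / rate
  }
  list(Q = Q, pi = pi, rate = rate)
}

# precomputed single-step codon pair structure, cached per code
codon_pair_structure <- local({
  cache <- new.env(parent = emptyenv())
  function(code) {
    key <- code$code_id
    if (!is.null(cache[[key]])) return(cache[[key]])
    sense <- code$sense_codons
    n <- length(sense)
    chars <- do.call(rbind, strsplit(sense, ""))
    purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    ii <- integer(0); jj <- integer(0)
    is_ts <- logical(0); is_ns <- logical(0)
    for (i in seq_len(n)) {
      diffs <- chars[i, 1] != chars[, 1]
      d <- (chars[i, 1] != chars[, 1]) + (chars[i, 2] != chars[, 2]) +
        (chars[i, 3] != chars[, 3])
      nb <- which(d == 1L)
      for (j in nb) {
        p <- which(chars[i, ] != chars[j, ])
        ii <- c(ii, i); jj <- c(jj, j)
        is_ts <- c(is_ts, purine[chars[i, p]] == purine[chars[j, p]])
        is_ns <- c(is_ns, code$aa[sense[i]] != code$aa[sense[j]])
      }
    }
    out <- list(i = ii, j = jj, pair_index = cbind(ii, jj),
                is_transition = unname(is_ts), is_nonsyn = unname(is_ns))
    cache[[key]] <- out
    out
  }
})

#' Transition probability matrix
#'
#' Matrix exponential `expm(Q t)` via symmetric eigen-decomposition of the
#' reversible generator.
#'
#' @param Q Rate matrix (list from [build_rate_matrix()] or a plain matrix
#'   with stationary frequencies `pi` supplied).
#' @param t Branch length (>= 0).
#' @param pi Stationary frequencies (taken from `Q` if it is a
#'   [build_rate_matrix()] result).
#' @return Stochastic matrix of the same dimension.
#' @export
transition_matrix <- function(Q, t, pi = NULL) {
  if (t < 0) stop("negative branch length")
  if (is.list(Q)) {
    pi <- Q$pi
    Q <- Q$Q
  }
  stopifnot(!is.null(pi))
  es <- eigen_reversible(Q, pi)
  P <- es$A %*% (exp(es$lambda * t) * es$B)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# eigen system of a reversible generator: P(t) = A diag(exp(lambda t)) B
# with A = D^{-1/2} U, B = U' D^{1/2}, D = diag(pi)
eigen_reversible <- function(Q, pi) {
  d <- sqrt(pi)
  # zero-frequency states would break the similarity transform
  d[d == 0] <- 1e-12
  S <- (d * Q) %*% diag(1 / d)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(A = diag(1 / d) %*% es$vectors,
       B = t(es$vectors) %*% diag(d),
       lambda = es$values)
}
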