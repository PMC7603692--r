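// Felsenstein pruning over sense-codon states with eigen-decomposed
// transition matrices.  P(t) = A diag(exp(lambda * t)) B where A, B absorb
// the sqrt(pi) symmetrising factors of the reversible generator; each
// (edge, site-class) pair maps to one eigen system (optionally a weighted
// mixture of two, for per-branch episodic models).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat pmat_from_eigen(const arma::mat& A, const arma::mat& B,
                                 const arma::vec& lam, double t) {
  arma::mat P = A * arma::diagmat(arma::exp(lam * t)) * B;
  // numerical guard: exact zeros are fine, small negatives are round-off
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// tipL:    nstate x nsites x ntip cube of tip partial likelihoods
// edge:    nedge x 2 (parent, child), POSTORDER, 1-based node ids with tips
//          1..ntip and root = ntip + 1 (ape convention)
// A,B,lam: lists of eigen systems (one per unique generator)
// map1:    nedge x nclass, 1-based index into A/B/lam
// tlen1:   nedge x nclass effective branch lengths (rate-scaled)
// map2:    like map1, or 0 where no second mixture component
// tlen2:   effective lengths for component 2
// mixw:    nclass weights on component 2 (per-branch mixture, episodic)
// rootfreq: nstate x nclass root frequencies
// returns: nsites x nclass matrix of per-site log-likelihoods
// [[Rcpp::export]]
arma::mat codon_loglik_cpp(const arma::cube& tipL,
                           const arma::imat& edge,
                           const int ntip,
                           const int nnode,
                           const List& A, const List& B, const List& lam,
                           const arma::imat& map1, const arma::mat& tlen1,
                           const arma::imat& map2, const arma::mat& tlen2,
                           const arma::vec& mixw,
                           const arma::mat& rootfreq) {
  const arma::uword nstate = tipL.n_rows;
  const arma::uword S = tipL.n_cols;
  const arma::uword nedge = edge.n_rows;
  const arma::uword nclass = map1.n_cols;
  const int root = ntip + 1;
  const arma::uword ntot = ntip + nnode;

  arma::mat out(S, nclass);

  std::vector<arma::mat> Amats(A.size()), Bmats(B.size());
  std::vector<arma::vec> lams(lam.size());
  for (int k = 0; k < A.size(); ++k) {
    Amats[k] = as<arma::mat>(A[k]);
    Bmats[k] = as<arma::mat>(B[k]);
    lams[k] = as<arma::vec>(lam[k]);
  }

  arma::cube part(nstate, S, ntot);
  for (arma::uword c = 0; c < nclass; ++c) {
    part.slices(0, ntip - 1) = tipL;
    part.slices(ntip, ntot - 1).ones();
    arma::rowvec logscale(S, arma::fill::zeros);

    for (arma::uword e = 0; e < nedge; ++e) {
      const int par = edge(e, 0) - 1;
      const int ch = edge(e, 1) - 1;
      const int k1 = map1(e, c) - 1;
      arma::mat P = pmat_from_eigen(Amats[k1], Bmats[k1], lams[k1],
                                    tlen1(e, c));
      const double w2 = mixw(c);
      if (w2 > 0.0 && map2(e, c) > 0) {
        const int k2 = map2(e, c) - 1;
        P = (1.0 - w2) * P +
            w2 * pmat_from_eigen(Amats[k2], Bmats[k2], lams[k2], tlen2(e, c));
      }
      arma::mat msg = P * part.slice(ch);
      part.slice(par) %= msg;
      // rescale the parent to avoid underflow
      arma::rowvec mx = arma::max(part.slice(par), 0);
      for (arma::uword s = 0; s < S; ++s) {
        if (mx(s) > 0.0 && mx(s) < 1e-200) {
          part.slice(par).col(s) /= mx(s);
          logscale(s) += std::log(mx(s));
        }
      }
    }
    arma::rowvec Ls = rootfreq.col(c).t() * part.slice(root - 1);
    for (arma::uword s = 0; s < S; ++s)
      out(s, c) = std::log(Ls(s)) + logscale(s);
  }
  return out;
}
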