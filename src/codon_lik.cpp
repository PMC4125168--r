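// Core numerics for the Goldman-Yang codon model: rate-matrix construction,
// transition probabilities by symmetrized eigendecomposition, and Felsenstein
// pruning over the 61 sense codons. Branch lengths are in expected
// substitutions per codon (the generator is rescaled so that the equilibrium
// flux equals one).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// pairs: one row per unordered single-nucleotide codon pair
//   col 0: i (0-based), col 1: j, col 2: transition flag, col 3: synonymous flag
static arma::mat gy94_Q(double kappa, double omega, const arma::vec& pi,
                        const arma::imat& pairs) {
  const arma::uword n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (arma::uword r = 0; r < pairs.n_rows; ++r) {
    const int i = pairs(r, 0), j = pairs(r, 1);
    const double rate = (pairs(r, 2) ? kappa : 1.0) * (pairs(r, 3) ? 1.0 : omega);
    Q(i, j) = rate * pi(j);
    Q(j, i) = rate * pi(i);
  }
  Q.diag() = -arma::sum(Q, 1);
  const double scale = -arma::dot(pi, Q.diag());
  if (!(scale > 0.0)) stop("degenerate rate matrix: zero equilibrium flux");
  return Q / scale;
}

struct EigQ {
  arma::vec lam;
  arma::mat V;      // eigenvectors of the symmetrized generator
  arma::vec sqp;    // sqrt(pi)
  arma::mat pmat(double t) const {
    arma::mat E = V * arma::diagmat(arma::exp(lam * t)) * V.t();
    arma::mat P = E;
    P.each_col() /= sqp;     // diag(1/sqrt(pi)) * E
    P.each_row() %= sqp.t(); // ... * diag(sqrt(pi))
    P.elem(arma::find(P < 0.0)).zeros();
    return P;
  }
};

static EigQ eig_gy94(double kappa, double omega, const arma::vec& pi,
                     const arma::imat& pairs) {
  arma::mat Q = gy94_Q(kappa, omega, pi, pairs);
  EigQ e;
  e.sqp = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= e.sqp;     // diag(sqrt(pi)) * Q
  B.each_row() /= e.sqp.t(); // ... * diag(1/sqrt(pi))
  B = 0.5 * (B + B.t());     // symmetric up to roundoff
  if (!arma::eig_sym(e.lam, e.V, B)) stop("eigendecomposition failed");
  return e;
}

// [[Rcpp::export]]
arma::mat codon_Q_cpp(double kappa, double omega, const arma::vec& pi,
                      const arma::imat& pairs) {
  return gy94_Q(kappa, omega, pi, pairs);
}

// [[Rcpp::export]]
arma::mat codon_pmat_cpp(double kappa, double omega, const arma::vec& pi,
                         const arma::imat& pairs, double t) {
  if (t < 0) stop("negative branch length");
  return eig_gy94(kappa, omega, pi, pairs).pmat(t);
}

// Felsenstein pruning.
//   tips:      ntip x nsites, 0-based codon state, -1 for missing
//   edge:      nedge x 2 matrix of 1-based node ids in ape postorder
//   edge_len:  branch lengths (substitutions/codon)
//   edge_class:0-based omega-class index per edge
//   omegas:    one omega per class
// [[Rcpp::export]]
List codon_lnL_cpp(const arma::imat& tips, const arma::imat& edge,
                   const arma::vec& edge_len, const arma::ivec& edge_class,
                   double kappa, const arma::vec& omegas, const arma::vec& pi,
                   const arma::imat& pairs) {
  const arma::uword ntip = tips.n_rows, nsites = tips.n_cols;
  const arma::uword nstate = pi.n_elem;
  const arma::uword nedge = edge.n_rows;
  arma::uword nnode = ntip;
  for (arma::uword e = 0; e < nedge; ++e) {
    nnode = std::max(nnode, (arma::uword) edge(e, 0));
    nnode = std::max(nnode, (arma::uword) edge(e, 1));
  }

  std::vector<EigQ> eigs;
  const int nclass = omegas.n_elem;
  eigs.reserve(nclass);
  for (int k = 0; k < nclass; ++k)
    eigs.push_back(eig_gy94(kappa, omegas(k), pi, pairs));

  std::vector<arma::mat> part(nnode);
  std::vector<arma::rowvec> lsc(nnode);
  for (arma::uword v = 0; v < ntip; ++v) {
    part[v].zeros(nstate, nsites);
    for (arma::uword s = 0; s < nsites; ++s) {
      const int st = tips(v, s);
      if (st < 0) part[v].col(s).ones();
      else part[v](st, s) = 1.0;
    }
    lsc[v].zeros(nsites);
  }

  for (arma::uword e = 0; e < nedge; ++e) {
    const arma::uword par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    if (part[par].n_elem == 0) {
      part[par].ones(nstate, nsites);
      lsc[par].zeros(nsites);
    }
    const int k = edge_class(e);
    if (k < 0 || k >= nclass) stop("edge class out of range");
    arma::mat P = eigs[k].pmat(edge_len(e));
    part[par] %= (P * part[ch]);
    lsc[par] += lsc[ch];
    // rescale to dodge underflow on deep trees
    arma::rowvec m = arma::max(part[par], 0);
    for (arma::uword s = 0; s < nsites; ++s) {
      if (m(s) > 0.0 && m(s) < 1e-60) {
        part[par].col(s) /= m(s);
        lsc[par](s) += std::log(m(s));
      }
    }
  }

  const arma::uword root = edge(nedge - 1, 0) - 1;
  arma::rowvec site = arma::log(pi.t() * part[root]) + lsc[root];
  return List::create(_["lnL"] = arma::accu(site),
                      _["site_lnL"] = NumericVector(site.begin(), site.end()));
}
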