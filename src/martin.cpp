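// Batched Martin distances between observability subspaces.
//
// The solver needs, at every outer iteration, the squared Martin distance
// from every modelled grid position to every sampled reference model
// (|grid| x |samples| per region).  Each distance is an SVD of an n x n
// crossproduct of orthonormal bases; the per-call overhead of doing this
// from R dominates, so the pairwise sweep lives here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Squared Martin distance between two orthonormal bases (pn x n).
// d^2 = -sum(log(cos^2 theta_i)), singular values clamped to [0, 1];
// any cos^2 below `tiny` means an orthogonal direction -> +Inf, which the
// caller clamps to `cap` (cap <= 0 disables clamping, returning Inf).
static double martin_sq(const arma::mat& Q1, const arma::mat& Q2,
                        double cap, double tiny = 1e-300) {
  arma::vec s = arma::svd(Q1.t() * Q2);
  double d2 = 0.0;
  for (arma::uword i = 0; i < s.n_elem; ++i) {
    double c = s(i);
    if (c > 1.0) c = 1.0;
    if (c < 0.0) c = 0.0;
    double c2 = c * c;
    if (c2 < tiny) {
      return (cap > 0.0) ? cap : R_PosInf;
    }
    d2 -= std::log(c2);
  }
  if (cap > 0.0 && d2 > cap) d2 = cap;
  if (d2 < 0.0) d2 = 0.0;  // fp guard: identical subspaces
  return d2;
}

// Q: (pn) x (n * M) matrix holding M orthonormal bases side by side.
// ia, ib: 1-based model indices. Returns |ia| x |ib| matrix of squared
// distances, clamped at cap (cap <= 0: no clamp, Inf allowed).
// [[Rcpp::export(name = ".cpp_martin_cross")]]
NumericMatrix cpp_martin_cross(const arma::mat& Q, int n,
                               const IntegerVector& ia,
                               const IntegerVector& ib,
                               double cap) {
  const int na = ia.size(), nb = ib.size();
  NumericMatrix out(na, nb);
  for (int j = 0; j < nb; ++j) {
    arma::mat Qb = Q.cols((ib[j] - 1) * n, ib[j] * n - 1);
    for (int i = 0; i < na; ++i) {
      if (ia[i] == ib[j]) { out(i, j) = 0.0; continue; }
      arma::mat Qa = Q.cols((ia[i] - 1) * n, ia[i] * n - 1);
      out(i, j) = martin_sq(Qa, Qb, cap);
    }
  }
  return out;
}
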