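// Brute-force nearest-neighbour queries for ICP (cloud sizes here are a
// few hundred points, so O(N*M) beats tree construction overhead).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// For each row of src, index (1-based) of nearest row of tgt and squared
// distance.
// [[Rcpp::export]]
List cpp_nearest(const arma::mat& src, const arma::mat& tgt) {
  const arma::uword N = src.n_rows, M = tgt.n_rows;
  IntegerVector idx(N);
  NumericVector d2(N);
  for (arma::uword i = 0; i < N; ++i) {
    double best = arma::datum::inf;
    arma::uword bj = 0;
    const double sx = src(i, 0), sy = src(i, 1), sz = src(i, 2);
    for (arma::uword j = 0; j < M; ++j) {
      const double dx = sx - tgt(j, 0), dy = sy - tgt(j, 1),
                   dz = sz - tgt(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    idx[i] = bj + 1;
    d2[i] = best;
  }
  return List::create(_["index"] = idx, _["dist2"] = d2);
}
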