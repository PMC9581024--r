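// Gaussian splatting of 2D point sets onto a pixel grid, with analytic
// gradients w.r.t. point positions and sigma. Coordinates are in pixels,
// pixel centres at half-integers; world<->pixel mapping lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// points: N x 2 (u, v) pixel coords; image is H x W, out(row, col) where
// row indexes v (y-down) and col indexes u. Each point contributes an
// unnormalised Gaussian (peak amplitude 1) truncated at trunc*sigma.
// [[Rcpp::export]]
arma::mat cpp_splat(const arma::mat& points, double sigma, int H, int W,
                    double trunc) {
  arma::mat img(H, W, arma::fill::zeros);
  const double r = trunc * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (arma::uword n = 0; n < points.n_rows; ++n) {
    const double u = points(n, 0), v = points(n, 1);
    int c0 = std::max(0, (int)std::floor(u - r - 0.5));
    int c1 = std::min(W - 1, (int)std::ceil(u + r - 0.5));
    int r0 = std::max(0, (int)std::floor(v - r - 0.5));
    int r1 = std::min(H - 1, (int)std::ceil(v + r - 0.5));
    for (int c = c0; c <= c1; ++c) {
      const double du = (c + 0.5) - u;
      for (int rr = r0; rr <= r1; ++rr) {
        const double dv = (rr + 0.5) - v;
        const double d2 = du * du + dv * dv;
        if (d2 <= r * r) img(rr, c) += std::exp(-d2 * inv2s2);
      }
    }
  }
  return img;
}

// Backward pass: G is the H x W upstream gradient dL/dpixels.
// Returns dL/dpoints (N x 2, pixel units) and dL/dsigma.
// [[Rcpp::export]]
List cpp_splat_backward(const arma::mat& points, double sigma, int H, int W,
                        double trunc, const arma::mat& G) {
  arma::mat dP(points.n_rows, 2, arma::fill::zeros);
  double dsigma = 0.0;
  const double r = trunc * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double invs2 = 1.0 / (sigma * sigma);
  const double invs3 = invs2 / sigma;
  for (arma::uword n = 0; n < points.n_rows; ++n) {
    const double u = points(n, 0), v = points(n, 1);
    int c0 = std::max(0, (int)std::floor(u - r - 0.5));
    int c1 = std::min(W - 1, (int)std::ceil(u + r - 0.5));
    int r0 = std::max(0, (int)std::floor(v - r - 0.5));
    int r1 = std::min(H - 1, (int)std::ceil(v + r - 0.5));
    double gu = 0.0, gv = 0.0;
    for (int c = c0; c <= c1; ++c) {
      const double du = (c + 0.5) - u;
      for (int rr = r0; rr <= r1; ++rr) {
        const double dv = (rr + 0.5) - v;
        const double d2 = du * du + dv * dv;
        if (d2 > r * r) continue;
        const double g = std::exp(-d2 * inv2s2) * G(rr, c);
        gu += g * du * invs2;
        gv += g * dv * invs2;
        dsigma += g * d2 * invs3;
      }
    }
    dP(n, 0) = gu;
    dP(n, 1) = gv;
  }
  return List::create(_["dpoints"] = dP, _["dsigma"] = dsigma);
}
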