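// Batched 3x3 strided convolutions via im2col + GEMM, with the backward
// pass needed to train the pose-regression network. Arrays are R 4D arrays
// laid out (H, W, C, B), column-major. Weights are Cout x (Cin*9) with
// column index ci*9 + kh*3 + kw; padding is fixed at 1 pixel.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_size(int n, int stride) {
  return (n + 2 - 3) / stride + 1;
}

static void im2col(const double* x, int H, int W, int C, int stride,
                   arma::mat& K) {
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  K.zeros(C * 9, Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = x + (size_t)H * W * ci;
        for (int kh = 0; kh < 3; ++kh) {
          const int h = ho * stride + kh - 1;
          if (h < 0 || h >= H) continue;
          for (int kw = 0; kw < 3; ++kw) {
            const int w = wo * stride + kw - 1;
            if (w < 0 || w >= W) continue;
            K(ci * 9 + kh * 3 + kw, p) = xc[h + (size_t)H * w];
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& K, int H, int W, int C, int stride,
                       double* dx) {
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const int p = ho + Ho * wo;
      for (int ci = 0; ci < C; ++ci) {
        double* xc = dx + (size_t)H * W * ci;
        for (int kh = 0; kh < 3; ++kh) {
          const int h = ho * stride + kh - 1;
          if (h < 0 || h >= H) continue;
          for (int kw = 0; kw < 3; ++kw) {
            const int w = wo * stride + kw - 1;
            if (w < 0 || w >= W) continue;
            xc[h + (size_t)H * w] += K(ci * 9 + kh * 3 + kw, p);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_forward(NumericVector x, const arma::mat& Wmat,
                               const arma::vec& bias, int stride) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Cout = Wmat.n_rows;
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  NumericVector out((size_t)Ho * Wo * Cout * B);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  arma::mat K;
  for (int b = 0; b < B; ++b) {
    im2col(REAL(x) + (size_t)H * W * C * b, H, W, C, stride, K);
    arma::mat O = Wmat * K;           // Cout x (Ho*Wo)
    O.each_col() += bias;
    double* op = REAL(out) + (size_t)Ho * Wo * Cout * b;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < Ho * Wo; ++p)
        op[p + (size_t)Ho * Wo * co] = O(co, p);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericVector x, const arma::mat& Wmat, int stride,
                       NumericVector dout) {
  IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], C = dims[2], B = dims[3];
  const int Cout = Wmat.n_rows;
  const int Ho = out_size(H, stride), Wo = out_size(W, stride);
  NumericVector dx((size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  arma::mat dW(arma::size(Wmat), arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat K, dO(Cout, Ho * Wo);
  for (int b = 0; b < B; ++b) {
    im2col(REAL(x) + (size_t)H * W * C * b, H, W, C, stride, K);
    const double* dp = REAL(dout) + (size_t)Ho * Wo * Cout * b;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < Ho * Wo; ++p)
        dO(co, p) = dp[p + (size_t)Ho * Wo * co];
    dW += dO * K.t();
    db += arma::sum(dO, 1);
    arma::mat dK = Wmat.t() * dO;     // (C*9) x (Ho*Wo)
    col2im_acc(dK, H, W, C, stride, REAL(dx) + (size_t)H * W * C * b);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}
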