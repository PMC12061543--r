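// 3x3 same-padding convolution forward/backward on (C, H*W) feature
// matrices (pixels in column-major raster order), via im2col + GEMM,
// with optional fused leaky-ReLU (slope 0.1) activation.
// Single-threaded BLAS keeps results bit-reproducible run to run.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// col(9*Cin, HW): rows blocked by the 9 offsets (dx, dy) in the fixed
// order dx = -1..1 outer, dy = -1..1 inner; zero padding outside.
static void im2col3(const arma::mat &X, int H, int W, arma::mat &col) {
  int Cin = X.n_rows;
  col.zeros(9 * Cin, (arma::uword)H * W);
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);   // output rows
      int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);   // output cols
      for (int c = c0; c < c1; ++c) {
        const double *src = X.colptr((arma::uword)(c + dx) * H + (r0 + dy));
        double *dst = col.colptr((arma::uword)c * H + r0) + (arma::uword)k * Cin;
        for (int r = r0; r < r1; ++r) {
          std::memcpy(dst, src, Cin * sizeof(double));
          src += Cin;
          dst += 9 * Cin;
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fwd(const arma::mat &X, int H, int W, const arma::mat &Wt,
                        const arma::vec &b, bool relu) {
  arma::mat col;
  im2col3(X, H, W, col);
  arma::mat out = Wt * col;
  out.each_col() += b;
  if (relu) out.transform([](double v) { return v > 0.0 ? v : 0.1 * v; });
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::mat &X, int H, int W, const arma::mat &Wt,
                   const arma::mat &dZ, bool need_dX) {
  arma::mat col;
  im2col3(X, H, W, col);
  arma::mat dW = dZ * col.t();
  arma::vec db = arma::sum(dZ, 1);
  if (!need_dX) return List::create(_["dW"] = dW, _["db"] = db);
  arma::mat dcol = Wt.t() * dZ;
  int Cin = X.n_rows;
  arma::mat dX(Cin, (arma::uword)H * W, arma::fill::zeros);
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++k) {
      int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
      int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);
      for (int c = c0; c < c1; ++c) {
        double *dst = dX.colptr((arma::uword)(c + dx) * H + (r0 + dy));
        const double *src = dcol.colptr((arma::uword)c * H + r0) + (arma::uword)k * Cin;
        for (int r = r0; r < r1; ++r) {
          for (int i = 0; i < Cin; ++i) dst[i] += src[i];
          dst += Cin;
          src += 9 * Cin;
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}
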