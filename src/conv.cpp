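// Dilated "same"-padding 2-D convolution kernels (forward, backward).
//
// Tensors arrive from R as dense column-major arrays in channels-last
// layout (H, W, N, C); kernels as (k, k, C, O). The convolution is
// computed by explicit im2col into an Armadillo matrix followed by one
// BLAS GEMM; the backward pass rebuilds the patch matrix from the cached
// input, so only the input itself needs to be retained between passes.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

// Copy x (H, W, N, C) into a zero-padded (H+2p, W+2p, N, C) buffer.
arma::vec pad_input(const double* x, int H, int W, int N, int C, int p) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  arma::vec xp(static_cast<arma::uword>(Hp) * Wp * N * C, arma::fill::zeros);
  double* xpd = xp.memptr();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < W; ++w) {
        const double* src = x + static_cast<size_t>(H) * (w + static_cast<size_t>(W) * (n + static_cast<size_t>(N) * c));
        double* dst = xpd + p + static_cast<size_t>(Hp) * ((w + p) + static_cast<size_t>(Wp) * (n + static_cast<size_t>(N) * c));
        std::copy(src, src + H, dst);
      }
  return xp;
}

// Patch matrix M: (H*W*N) x (k*k*C); column (ki, kj, c) holds the input
// window shifted by the kernel offset, matching matrix(W, k*k*C, O) in R.
arma::mat build_patches(const arma::vec& xp, int H, int W, int N, int C,
                        int k, int dil, int p) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  arma::mat M(static_cast<arma::uword>(H) * W * N, static_cast<arma::uword>(k) * k * C);
  const double* xpd = xp.memptr();
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        double* col = M.colptr(ki + k * kj + k * k * c);
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < W; ++w) {
            const double* src = xpd + ki * dil +
              static_cast<size_t>(Hp) * ((w + kj * dil) + static_cast<size_t>(Wp) * (n + static_cast<size_t>(N) * c));
            std::copy(src, src + H, col + static_cast<size_t>(H) * (w + static_cast<size_t>(W) * n));
          }
      }
  return M;
}

} // namespace

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector W, NumericVector b,
                         int dilation) {
  IntegerVector dx = x.attr("dim"), dw = W.attr("dim");
  const int H = dx[0], Wd = dx[1], N = dx[2], C = dx[3];
  const int k = dw[0], O = dw[3];
  const int p = (k - 1) / 2 * dilation;
  arma::vec xp = pad_input(x.begin(), H, Wd, N, C, p);
  arma::mat M = build_patches(xp, H, Wd, N, C, k, dilation, p);
  arma::mat Wm(W.begin(), static_cast<arma::uword>(k) * k * C, O, false);
  arma::mat Y = M * Wm;
  Y.each_row() += arma::rowvec(b.begin(), O, false);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(H, Wd, N, O);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector W, NumericVector dy,
                int dilation) {
  IntegerVector dx = x.attr("dim"), dw = W.attr("dim");
  const int H = dx[0], Wd = dx[1], N = dx[2], C = dx[3];
  const int k = dw[0], O = dw[3];
  const int p = (k - 1) / 2 * dilation;
  const arma::uword rows = static_cast<arma::uword>(H) * Wd * N;
  arma::mat dyM(dy.begin(), rows, O, false);
  arma::vec xp = pad_input(x.begin(), H, Wd, N, C, p);
  arma::mat M = build_patches(xp, H, Wd, N, C, k, dilation, p);
  arma::mat Wm(W.begin(), static_cast<arma::uword>(k) * k * C, O, false);
  arma::mat gW = M.t() * dyM;
  arma::rowvec gb = arma::sum(dyM, 0);
  arma::mat dxM = dyM * Wm.t();     // rows x (k*k*C)
  // col2im: scatter-add patch gradients back into the padded frame
  const int Hp = H + 2 * p, Wp = Wd + 2 * p;
  arma::vec dxp(static_cast<arma::uword>(Hp) * Wp * N * C, arma::fill::zeros);
  double* dxpd = dxp.memptr();
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const double* col = dxM.colptr(ki + k * kj + k * k * c);
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < Wd; ++w) {
            double* dst = dxpd + ki * dilation +
              static_cast<size_t>(Hp) * ((w + kj * dilation) + static_cast<size_t>(Wp) * (n + static_cast<size_t>(N) * c));
            const double* src = col + static_cast<size_t>(H) * (w + static_cast<size_t>(Wd) * n);
            for (int h = 0; h < H; ++h) dst[h] += src[h];
          }
      }
  // crop the padding
  NumericVector dxo(static_cast<R_xlen_t>(H) * Wd * N * C);
  double* dxod = dxo.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wd; ++w) {
        const double* src = dxpd + p + static_cast<size_t>(Hp) * ((w + p) + static_cast<size_t>(Wp) * (n + static_cast<size_t>(N) * c));
        double* dst = dxod + static_cast<size_t>(H) * (w + static_cast<size_t>(Wd) * (n + static_cast<size_t>(N) * c));
        std::copy(src, src + H, dst);
      }
  dxo.attr("dim") = IntegerVector::create(H, Wd, N, C);
  NumericVector gWo(gW.begin(), gW.end());
  gWo.attr("dim") = dw;
  return List::create(Named("dx") = dxo, Named("dW") = gWo,
                      Named("db") = NumericVector(gb.begin(), gb.end()));
}
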