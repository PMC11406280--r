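#include <Rcpp.h>
using namespace Rcpp;

// Tensor layout throughout: x is a flat vector for an array of dim (C, H, W, N),
// channel index fastest (column-major R array). im2col emits a (C*k*k) x
// (oH*oW*N) matrix whose rows run c fastest, then kh, then kw, and whose
// columns run oh fastest, then ow, then n, so that W (F x C*k*k) %*% cols
// reshapes directly to an (F, oH, oW, N) array.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(C * k * k, oH * oW * N);
  double *po = out.begin();
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const R_xlen_t col = (R_xlen_t)oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * n);
        double *pc = po + col * (R_xlen_t)(C * k * k);
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow * stride + kw - pad;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh * stride + kh - pad;
            double *dst = pc + C * (kh + k * kw);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double *src = px + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add columns back into the (C, H, W, N) input.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int C, int H, int W, int N,
                         int k, int stride, int pad) {
  const int oH = (H + 2 * pad - k) / stride + 1;
  const int oW = (W + 2 * pad - k) / stride + 1;
  NumericVector x((R_xlen_t)C * H * W * N);
  double *px = x.begin();
  const double *pc0 = cols.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        const R_xlen_t col = (R_xlen_t)oh + (R_xlen_t)oH * (ow + (R_xlen_t)oW * n);
        const double *pc = pc0 + col * (R_xlen_t)(C * k * k);
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow * stride + kw - pad;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh * stride + kh - pad;
            if (h < 0 || h >= H) continue;
            const double *src = pc + C * (kh + k * kw);
            double *dst = px + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return x;
}
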