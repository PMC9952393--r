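// im2col / col2im kernels for the convolution layers. Tensors use the
// package's (H, W, N, C) column-major layout; the col matrix has one row
// per output pixel (ho fastest, then wo, then n) and kh*kw blocks of Cin
// columns, block index dh + kh*dw. Zero padding is folded into the gather
// and scatter so no padded copy is ever materialized.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
SEXP im2col_cpp(NumericVector x, int H, int W, int N, int C,
                int kh, int kw, int stride, int pad, int Ho, int Wo) {
  const R_xlen_t rows = (R_xlen_t)Ho * Wo * N;
  SEXP colS = PROTECT(Rf_allocMatrix(REALSXP, rows, kh * kw * C));
  const double *px = REAL(x);
  double *pc = REAL(colS);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int b = dh + kh * dw;
        double *dst = pc + ((R_xlen_t)b * C + c) * rows;
        // valid output range along each axis for this kernel offset
        for (int n = 0; n < N; ++n) {
          const double *src = px + ((R_xlen_t)c * N + n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wsrc = dw + stride * wo - pad;
            double *d0 = dst + ((R_xlen_t)n * Wo + wo) * Ho;
            if (wsrc < 0 || wsrc >= W) {
              std::memset(d0, 0, sizeof(double) * Ho);
              continue;
            }
            const double *s0 = src + (R_xlen_t)wsrc * H;
            if (stride == 1) {
              // contiguous run: hsrc = dh + ho - pad in [0, H)
              int lo = pad - dh; if (lo < 0) lo = 0;
              int hi = H - dh + pad; if (hi > Ho) hi = Ho;
              if (lo > 0) std::memset(d0, 0, sizeof(double) * lo);
              if (hi > lo)
                std::memcpy(d0 + lo, s0 + dh + lo - pad,
                            sizeof(double) * (hi - lo));
              if (hi < Ho)
                std::memset(d0 + hi, 0, sizeof(double) * (Ho - hi));
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hsrc = dh + stride * ho - pad;
                d0[ho] = (hsrc < 0 || hsrc >= H) ? 0.0 : s0[hsrc];
              }
            }
          }
        }
      }
    }
  }
  UNPROTECT(1);
  return colS;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix gcol, int H, int W, int N, int C,
                         int kh, int kw, int stride, int pad,
                         int Ho, int Wo) {
  NumericVector gx((R_xlen_t)H * W * N * C);
  const double *pc = gcol.begin();
  double *px = gx.begin();
  const R_xlen_t rows = (R_xlen_t)Ho * Wo * N;
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int b = dh + kh * dw;
        const double *src = pc + ((R_xlen_t)b * C + c) * rows;
        for (int n = 0; n < N; ++n) {
          double *dst = px + ((R_xlen_t)c * N + n) * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wsrc = dw + stride * wo - pad;
            if (wsrc < 0 || wsrc >= W) continue;
            const double *s0 = src + ((R_xlen_t)n * Wo + wo) * Ho;
            double *d0 = dst + (R_xlen_t)wsrc * H;
            if (stride == 1) {
              int lo = pad - dh; if (lo < 0) lo = 0;
              int hi = H - dh + pad; if (hi > Ho) hi = Ho;
              const double *s1 = s0 + lo;
              double *d1 = d0 + dh + lo - pad;
              for (int k = 0; k < hi - lo; ++k) d1[k] += s1[k];
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hsrc = dh + stride * ho - pad;
                if (hsrc >= 0 && hsrc < H) d0[hsrc] += s0[ho];
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(H, W, N, C);
  return gx;
}
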