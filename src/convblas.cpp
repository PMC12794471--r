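// Convolution engine: per-image im2col into a small reusable buffer plus
// BLAS dgemm.  The patch matrix of one image stays cache-resident instead of
// being materialised for the whole batch, which matters because these
// feature tensors are far larger than the flop counts suggest.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// im2col of ONE image plane set (H x W x C, column-major) into buf
// [oH*oW, kh*kw*C], rows pixel-fastest.
static void im2col_one(const double *x, int H, int W, int C,
                       int kh, int kw, int stride, int ph, int pw,
                       int oH, int oW, double *buf) {
  const R_xlen_t plane = (R_xlen_t)oH * oW;
  for (int c = 0; c < C; ++c) {
    const double *xc = x + (R_xlen_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        double *col = buf + ((R_xlen_t)(di + kh * dj) + (R_xlen_t)kh * kw * c) * plane;
        for (int j = 0; j < oW; ++j) {
          const int w = j * stride - pw + dj;
          double *dst = col + (R_xlen_t)j * oH;
          if (w < 0 || w >= W) {
            for (int i = 0; i < oH; ++i) dst[i] = 0.0;
          } else {
            const double *src = xc + (R_xlen_t)w * H;
            for (int i = 0; i < oH; ++i) {
              const int h = i * stride - ph + di;
              dst[i] = (h < 0 || h >= H) ? 0.0 : src[h];
            }
          }
        }
      }
    }
  }
}

// adjoint: scatter-add buf back onto one image
static void col2im_one(const double *buf, int H, int W, int C,
                       int kh, int kw, int stride, int ph, int pw,
                       int oH, int oW, double *x) {
  const R_xlen_t plane = (R_xlen_t)oH * oW;
  for (int c = 0; c < C; ++c) {
    double *xc = x + (R_xlen_t)c * H * W;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const double *col = buf + ((R_xlen_t)(di + kh * dj) + (R_xlen_t)kh * kw * c) * plane;
        for (int j = 0; j < oW; ++j) {
          const int w = j * stride - pw + dj;
          if (w < 0 || w >= W) continue;
          const double *src = col + (R_xlen_t)j * oH;
          double *dst = xc + (R_xlen_t)w * H;
          for (int i = 0; i < oH; ++i) {
            const int h = i * stride - ph + di;
            if (h >= 0 && h < H) dst[h] += src[i];
          }
        }
      }
    }
  }
}

static void dgemm(const char *ta, const char *tb, int m, int n, int k,
                  double alpha, const double *A, int lda, const double *B,
                  int ldb, double beta, double *C, int ldc) {
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

// Strided convolution: x [H, W, C, B], Wmat [kh*kw*C, M] -> out [oH, oW, M, B].
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, int H, int W, int C, int B,
                           NumericMatrix Wmat, int kh, int kw, int stride,
                           int ph, int pw, int oH, int oW) {
  const int K = kh * kw * C;
  const int M = Wmat.ncol();
  const R_xlen_t plane = (R_xlen_t)oH * oW;
  NumericVector out(no_init(plane * M * B));
  std::vector<double> buf((size_t)plane * K);
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + (R_xlen_t)b * H * W * C;
    im2col_one(xb, H, W, C, kh, kw, stride, ph, pw, oH, oW, buf.data());
    dgemm("N", "N", (int)plane, M, K, 1.0, buf.data(), (int)plane,
          Wmat.begin(), K, 0.0, out.begin() + (R_xlen_t)b * plane * M,
          (int)plane);
  }
  return out;
}

// Gradients of the convolution: returns dx [H, W, C, B] and dW [K, M].
// dY is in the output layout [oH, oW, M, B].
// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector dY, int H, int W, int C,
                  int B, NumericMatrix Wmat, int kh, int kw, int stride,
                  int ph, int pw, int oH, int oW) {
  const int K = kh * kw * C;
  const int M = Wmat.ncol();
  const R_xlen_t plane = (R_xlen_t)oH * oW;
  NumericVector dx((R_xlen_t)H * W * C * B);          // zero-filled: scatter target
  NumericMatrix dW(K, M);                             // zero-filled: accumulator
  std::vector<double> buf((size_t)plane * K);
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + (R_xlen_t)b * H * W * C;
    const double *dyb = dY.begin() + (R_xlen_t)b * plane * M;
    // dW += im2col(x_b)^T . dY_b
    im2col_one(xb, H, W, C, kh, kw, stride, ph, pw, oH, oW, buf.data());
    dgemm("T", "N", K, M, (int)plane, 1.0, buf.data(), (int)plane,
          dyb, (int)plane, 1.0, dW.begin(), K);
    // dx_b = col2im(dY_b . W^T)
    dgemm("N", "T", (int)plane, K, M, 1.0, dyb, (int)plane,
          Wmat.begin(), K, 0.0, buf.data(), (int)plane);
    col2im_one(buf.data(), H, W, C, kh, kw, stride, ph, pw, oH, oW,
               dx.begin() + (R_xlen_t)b * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW);
}

// Transposed convolution (exact adjoint of cpp_conv_fwd with the same
// kernel): x [oH, oW, M, B] on the coarse grid -> out [H, W, C_up, B] where
// C_up = nrow(Wmat) / (kh*kw).
// [[Rcpp::export]]
NumericVector cpp_deconv_fwd(NumericVector x, int oH, int oW, int B,
                             NumericMatrix Wmat, int kh, int kw, int stride,
                             int ph, int pw, int H, int W) {
  const int K = Wmat.nrow();
  const int M = Wmat.ncol();
  const int C = K / (kh * kw);
  const R_xlen_t plane = (R_xlen_t)oH * oW;
  NumericVector out((R_xlen_t)H * W * C * B);         // zero-filled: scatter target
  std::vector<double> buf((size_t)plane * K);
  for (int b = 0; b < B; ++b) {
    const double *xb = x.begin() + (R_xlen_t)b * plane * M;
    dgemm("N", "T", (int)plane, K, M, 1.0, xb, (int)plane,
          Wmat.begin(), K, 0.0, buf.data(), (int)plane);
    col2im_one(buf.data(), H, W, C, kh, kw, stride, ph, pw, oH, oW,
               out.begin() + (R_xlen_t)b * H * W * C);
  }
  return out;
}

// Gradients of the transposed convolution: dOut lives on the fine grid
// [H, W, C_up, B]; returns dx [oH, oW, M, B] and dW [K, M].
// [[Rcpp::export]]
List cpp_deconv_bwd(NumericVector x, NumericVector dOut, int oH, int oW,
                    int B, NumericMatrix Wmat, int kh, int kw, int stride,
                    int ph, int pw, int H, int W) {
  const int K = Wmat.nrow();
  const int M = Wmat.ncol();
  const int C = K / (kh * kw);
  const R_xlen_t plane = (R_xlen_t)oH * oW;
  NumericVector dx(no_init(plane * M * B));
  NumericMatrix dW(K, M);
  std::vector<double> buf((size_t)plane * K);
  for (int b = 0; b < B; ++b) {
    const double *dob = dOut.begin() + (R_xlen_t)b * H * W * C;
    const double *xb = x.begin() + (R_xlen_t)b * plane * M;
    im2col_one(dob, H, W, C, kh, kw, stride, ph, pw, oH, oW, buf.data());
    // dx_b = im2col(dOut_b) . W
    dgemm("N", "N", (int)plane, M, K, 1.0, buf.data(), (int)plane,
          Wmat.begin(), K, 0.0, dx.begin() + (R_xlen_t)b * plane * M,
          (int)plane);
    // dW += im2col(dOut_b)^T . x_b
    dgemm("T", "N", K, M, (int)plane, 1.0, buf.data(), (int)plane,
          xb, (int)plane, 1.0, dW.begin(), K);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW);
}
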