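#include <Rcpp.h>
using namespace Rcpp;

// Non-overlapping f x f block means over the leading two axes of an
// [H, W, K] stack (K = everything else flattened).
// [[Rcpp::export]]
NumericVector cpp_avgpool(NumericVector x, int H, int W, int K, int f) {
  const int oH = H / f, oW = W / f;
  NumericVector out(no_init((R_xlen_t)oH * oW * K));
  const double *xp = x.begin();
  double *op = out.begin();
  const double inv = 1.0 / (f * f);
  for (int k = 0; k < K; ++k) {
    const double *xk = xp + (R_xlen_t)k * H * W;
    double *ok = op + (R_xlen_t)k * oH * oW;
    for (int j = 0; j < oW; ++j) {
      for (int i = 0; i < oH; ++i) {
        double acc = 0.0;
        for (int dj = 0; dj < f; ++dj) {
          const double *col = xk + (R_xlen_t)(j * f + dj) * H + i * f;
          for (int di = 0; di < f; ++di) acc += col[di];
        }
        ok[i + (R_xlen_t)j * oH] = acc * inv;
      }
    }
  }
  return out;
}

// Adjoint of cpp_avgpool up to scaling: spread each value uniformly over its
// f x f block, multiplied by `scale` (1/f^2 gives the exact mean-pool
// adjoint, used both for pooling backprop and block upsampling).
// [[Rcpp::export]]
NumericVector cpp_upsample(NumericVector x, int oH, int oW, int K, int f,
                           double scale) {
  const int H = oH * f, W = oW * f;
  NumericVector out(no_init((R_xlen_t)H * W * K));
  const double *xp = x.begin();
  double *op = out.begin();
  for (int k = 0; k < K; ++k) {
    const double *xk = xp + (R_xlen_t)k * oH * oW;
    double *ok = op + (R_xlen_t)k * H * W;
    for (int j = 0; j < oW; ++j) {
      for (int i = 0; i < oH; ++i) {
        const double v = xk[i + (R_xlen_t)j * oH] * scale;
        for (int dj = 0; dj < f; ++dj) {
          double *col = ok + (R_xlen_t)(j * f + dj) * H + i * f;
          for (int di = 0; di < f; ++di) col[di] = v;
        }
      }
    }
  }
  return out;
}

// Fused column-group affine: y = x * a[g] + b[g], where x is an
// [nspat, nchan*B] matrix viewed column-major and g = column %% nchan is the
// channel of that column.  Used by batch norm to avoid materialising the
// expanded per-channel vectors.
// [[Rcpp::export]]
NumericVector cpp_affine_chan(NumericVector x, int nspat, int nchan, int B,
                              NumericVector a, NumericVector b) {
  NumericVector y(no_init(x.size()));
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < nchan; ++c) {
      const double ac = a[c], bc = b[c];
      const R_xlen_t off = ((R_xlen_t)bb * nchan + c) * nspat;
      for (int i = 0; i < nspat; ++i) yp[off + i] = xp[off + i] * ac + bc;
    }
  }
  return y;
}

// Per-channel sums of x and x*w over an [nspat, nchan*B] matrix (channel =
// column %% nchan): one pass returning a 2 x nchan matrix (sum_x, sum_xw).
// [[Rcpp::export]]
NumericMatrix cpp_chan_sums2(NumericVector x, NumericVector w, int nspat,
                             int nchan, int B) {
  NumericMatrix out(2, nchan);
  const double *xp = x.begin(), *wp = w.begin();
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < nchan; ++c) {
      const R_xlen_t off = ((R_xlen_t)bb * nchan + c) * nspat;
      double s1 = 0.0, s2 = 0.0;
      for (int i = 0; i < nspat; ++i) {
        const double v = xp[off + i];
        s1 += v;
        s2 += v * wp[off + i];
      }
      out(0, c) += s1;
      out(1, c) += s2;
    }
  }
  return out;
}

// Single-pass batch-norm input gradient:
// dx = dym * g1[c] - c1[c] - xhat * c2[c]  (channel = column %% nchan).
// [[Rcpp::export]]
NumericVector cpp_bn_backward(NumericVector dym, NumericVector xhat,
                              int nspat, int nchan, int B,
                              NumericVector g1, NumericVector c1,
                              NumericVector c2) {
  NumericVector dx(no_init(dym.size()));
  const double *dp = dym.begin(), *hp = xhat.begin();
  double *op = dx.begin();
  for (int bb = 0; bb < B; ++bb) {
    for (int c = 0; c < nchan; ++c) {
      const double gc = g1[c], c1c = c1[c], c2c = c2[c];
      const R_xlen_t off = ((R_xlen_t)bb * nchan + c) * nspat;
      for (int i = 0; i < nspat; ++i) {
        op[off + i] = dp[off + i] * gc - c1c - hp[off + i] * c2c;
      }
    }
  }
  return dx;
}

// Mean over the orientation axis: x viewed as [nspat, O, K] -> [nspat, K].
// [[Rcpp::export]]
NumericVector cpp_project_fwd(NumericVector x, int nspat, int O, int K) {
  NumericVector out(no_init((R_xlen_t)nspat * K));
  const double *xp = x.begin();
  double *op = out.begin();
  const double inv = 1.0 / O;
  for (int k = 0; k < K; ++k) {
    double *ok = op + (R_xlen_t)k * nspat;
    const double *x0 = xp + (R_xlen_t)k * O * nspat;
    for (int i = 0; i < nspat; ++i) ok[i] = x0[i];
    for (int m = 1; m < O; ++m) {
      const double *xm = x0 + (R_xlen_t)m * nspat;
      for (int i = 0; i < nspat; ++i) ok[i] += xm[i];
    }
    for (int i = 0; i < nspat; ++i) ok[i] *= inv;
  }
  return out;
}

// Adjoint: broadcast dout / O over the orientation axis.
// [[Rcpp::export]]
NumericVector cpp_project_bwd(NumericVector dout, int nspat, int O, int K) {
  NumericVector dx(no_init((R_xlen_t)nspat * O * K));
  const double *dp = dout.begin();
  double *xp = dx.begin();
  const double inv = 1.0 / O;
  for (int k = 0; k < K; ++k) {
    const double *dk = dp + (R_xlen_t)k * nspat;
    for (int m = 0; m < O; ++m) {
      double *xm = xp + ((R_xlen_t)k * O + m) * nspat;
      for (int i = 0; i < nspat; ++i) xm[i] = dk[i] * inv;
    }
  }
  return dx;
}

// y = x * s[col] + add[col] for an [nspat, ncol] view (per-column gains,
// e.g. squeeze-excitation gates per channel and image).
// [[Rcpp::export]]
NumericVector cpp_scale_cols(NumericVector x, int nspat, int ncol,
                             NumericVector s, NumericVector add) {
  NumericVector y(no_init(x.size()));
  const double *xp = x.begin();
  double *yp = y.begin();
  for (int c = 0; c < ncol; ++c) {
    const double sc = s[c], ac = add[c];
    const R_xlen_t off = (R_xlen_t)c * nspat;
    for (int i = 0; i < nspat; ++i) yp[off + i] = xp[off + i] * sc + ac;
  }
  return y;
}

// Per-column dot products of two equally shaped [nspat, ncol] views.
// [[Rcpp::export]]
NumericVector cpp_dot_cols(NumericVector a, NumericVector b, int nspat,
                           int ncol) {
  NumericVector out(no_init(ncol));
  const double *ap = a.begin(), *bp = b.begin();
  for (int c = 0; c < ncol; ++c) {
    const R_xlen_t off = (R_xlen_t)c * nspat;
    double s = 0.0;
    for (int i = 0; i < nspat; ++i) s += ap[off + i] * bp[off + i];
    out[c] = s;
  }
  return out;
}

// Concatenate two batches along the channel axis: inputs [nspat, C1, B] and
// [nspat, C2, B] (flattened), output [nspat, C1 + C2, B].
// [[Rcpp::export]]
NumericVector cpp_concat_chan(NumericVector a, NumericVector b, int nspat,
                              int C1, int C2, int B) {
  NumericVector out(no_init((R_xlen_t)nspat * (C1 + C2) * B));
  double *op = out.begin();
  const double *ap = a.begin(), *bp = b.begin();
  const R_xlen_t blkA = (R_xlen_t)nspat * C1, blkB = (R_xlen_t)nspat * C2;
  for (int bb = 0; bb < B; ++bb) {
    memcpy(op + bb * (blkA + blkB), ap + bb * blkA, blkA * sizeof(double));
    memcpy(op + bb * (blkA + blkB) + blkA, bp + bb * blkB,
           blkB * sizeof(double));
  }
  return out;
}

// Inverse split (returns a list of the two channel blocks).
// [[Rcpp::export]]
List cpp_split_chan(NumericVector x, int nspat, int C1, int C2, int B) {
  NumericVector a(no_init((R_xlen_t)nspat * C1 * B));
  NumericVector b(no_init((R_xlen_t)nspat * C2 * B));
  const double *xp = x.begin();
  const R_xlen_t blkA = (R_xlen_t)nspat * C1, blkB = (R_xlen_t)nspat * C2;
  for (int bb = 0; bb < B; ++bb) {
    memcpy(a.begin() + bb * blkA, xp + bb * (blkA + blkB),
           blkA * sizeof(double));
    memcpy(b.begin() + bb * blkB, xp + bb * (blkA + blkB) + blkA,
           blkB * sizeof(double));
  }
  return List::create(_["a"] = a, _["b"] = b);
}

// Elementwise max(x, 0) and its gradient gate (mask recovered from the
// forward output, since out > 0 iff x > 0): pmax() in R is an order of
// magnitude slower on large feature tensors.
// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector x) {
  NumericVector y(no_init(x.size()));
  const double *xp = x.begin();
  double *yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0.0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dout, NumericVector out) {
  NumericVector dx(no_init(dout.size()));
  const double *dp = dout.begin(), *op = out.begin();
  double *xp = dx.begin();
  const R_xlen_t n = dout.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[i] = op[i] > 0.0 ? dp[i] : 0.0;
  return dx;
}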