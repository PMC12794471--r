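# Batched convolution engine.  Feature batches are stored as
# [H, W, C, B] (planar) or [H, W, O, C, B] (orientation) arrays; the latter is
# viewed as planar with O*C channels (identical memory layout), so one
# im2col/GEMM pair serves every convolution flavour.  The C++ core extracts
# patches per image into a cache-resident buffer and calls BLAS directly;
# backward passes recompute the patch buffer rather than caching it.
# Padding dialect: "same" keeps the extent at stride 1 (zero padding
# (k-1)/2), "valid" pads nothing.

conv_geometry <- function(H, W, kh, kw, stride, padding) {
  if (stride < 1) stopf("stride must be >= 1")
  if (padding == "same") {
    ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
    oH <- (H - 1) %/% stride + 1; oW <- (W - 1) %/% stride + 1
  } else if (padding == "valid") {
    ph <- 0L; pw <- 0L
    oH <- (H - kh) %/% stride + 1; oW <- (W - kw) %/% stride + 1
  } else stopf("unknown padding '%s' (use 'same' or 'valid')", padding)
  if (oH < 1 || oW < 1) stopf("kernel larger than padded input")
  list(ph = ph, pw = pw, oH = oH, oW = oW)
}

# Forward strided convolution of x [H, W, C, B] with a kernel bank
# Wmat [kh*kw*C, M]; returns out [oH, oW, M, B] plus what backward needs.
conv_forward <- function(x, Wmat, stride, padding, kh, kw) {
  d <- dim(x)
  g <- conv_geometry(d[1], d[2], kh, kw, stride, padding)
  out <- cpp_conv_fwd(x, d[1], d[2], d[3], d[4], Wmat, kh, kw,
                      as.integer(stride), g$ph, g$pw, g$oH, g$oW)
  dim(out) <- c(g$oH, g$oW, ncol(Wmat), d[4])
  list(out = out, x = x, geom = g, in_dim = d)
}

# Backward: gradients for the input and the (flattened) kernel bank.
conv_backward <- function(cache, Wmat, dout, stride, kh, kw) {
  d <- cache$in_dim
  g <- cache$geom
  r <- cpp_conv_bwd(cache$x, dout, d[1], d[2], d[3], d[4], Wmat, kh, kw,
                    as.integer(stride), g$ph, g$pw, g$oH, g$oW)
  dim(r$dx) <- d
  list(dx = r$dx, dW = r$dW)
}

# Transposed convolution (exact adjoint of conv_forward with the same kernel
# bank): maps x [oH, oW, M, B] on the coarse grid to [out_extent, C_up, B].
deconv_forward <- function(x, Wmat, stride, padding, kh, kw, out_extent) {
  d <- dim(x)
  g <- conv_geometry(out_extent[1], out_extent[2], kh, kw, stride, padding)
  if (g$oH != d[1] || g$oW != d[2]) {
    stopf("deconv geometry mismatch: conv(%dx%d) would give %dx%d, input is %dx%d",
          out_extent[1], out_extent[2], g$oH, g$oW, d[1], d[2])
  }
  Cup <- nrow(Wmat) %/% (kh * kw)
  up <- cpp_deconv_fwd(x, d[1], d[2], d[4], Wmat, kh, kw, as.integer(stride),
                       g$ph, g$pw, out_extent[1], out_extent[2])
  dim(up) <- c(out_extent[1], out_extent[2], Cup, d[4])
  list(out = up, x = x, geom = g, in_dim = d, out_extent = out_extent)
}

deconv_backward <- function(cache, Wmat, dout, stride, kh, kw) {
  d <- cache$in_dim
  g <- cache$geom
  r <- cpp_deconv_bwd(cache$x, dout, d[1], d[2], d[4], Wmat, kh, kw,
                      as.integer(stride), g$ph, g$pw,
                      cache$out_extent[1], cache$out_extent[2])
  dim(r$dx) <- d
  list(dx = r$dx, dW = r$dW)
}
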