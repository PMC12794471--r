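# The Mod-SE(2) layer zoo.  Two surfaces share one numerical core:
#  * user-facing single-sample operations (lifting_conv, group_conv, ...)
#    operating on [H, W, C] images and [H, W, O, C] orientation feature maps;
#  * an internal batched layer framework (init_layer / layer_forward /
#    layer_backward) used by the reference networks and the trainer, with
#    hand-written reverse-mode gradients.

# --- kernel bank construction ----------------------------------------------

# Lifting bank: columns hold the base kernel rotated to each orientation,
# interleaved so the output channel index is (orientation-fastest, filter).
lifting_bank <- function(w, O) {
  d <- dim(w)  # [kh, kw, Cin, Cout]
  khkw <- d[1] * d[2]
  Wall <- matrix(0, khkw * d[3], O * d[4])
  for (k in 0:(O - 1)) {
    M <- rotation_operator(d[1], d[2], 2 * pi * k / O)
    rk <- M %*% matrix(w, khkw)
    Wall[, k + 1 + (0:(d[4] - 1)) * O] <- matrix(rk, khkw * d[3], d[4])
  }
  Wall
}

lifting_bank_grad <- function(dWall, d, O) {
  khkw <- d[1] * d[2]
  dw <- matrix(0, khkw, d[3] * d[4])
  for (k in 0:(O - 1)) {
    M <- rotation_operator(d[1], d[2], 2 * pi * k / O)
    dk <- matrix(dWall[, k + 1 + (0:(d[4] - 1)) * O, drop = FALSE], khkw)
    dw <- dw + crossprod(M, dk)
  }
  array(dw, d)
}

# Group-convolution bank: column block k holds rotate_group_kernel(w, k).
group_bank <- function(w, orientation_shift = TRUE) {
  d <- dim(w)  # [kh, kw, O, Cin, Cout]
  O <- d[3]
  rows <- d[1] * d[2] * O * d[4]
  Wall <- matrix(0, rows, O * d[5])
  for (k in 0:(O - 1)) {
    wk <- rotate_group_kernel(w, k, orientation_shift)
    Wall[, k + 1 + (0:(d[5] - 1)) * O] <- matrix(wk, rows)
  }
  Wall
}

group_bank_grad <- function(dWall, d, orientation_shift = TRUE) {
  O <- d[3]
  rows <- d[1] * d[2] * O * d[4]
  dw <- array(0, d)
  for (k in 0:(O - 1)) {
    dk <- array(dWall[, k + 1 + (0:(d[5] - 1)) * O, drop = FALSE], d)
    dw <- dw + unrotate_group_kernel_grad(dk, k, orientation_shift)
  }
  dw
}

fold_o <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2], d[3] * d[4], d[5])
  x
}

unfold_o <- function(x, O) {
  d <- dim(x)
  dim(x) <- c(d[1], d[2], O, d[3] %/% O, d[4])
  x
}

# --- generic array helpers --------------------------------------------------

avgpool_fwd <- function(x, f) {
  d <- dim(x)
  if (d[1] %% f != 0 || d[2] %% f != 0) {
    stopf("spatial extent %dx%d is not divisible by pooling factor %d; pad the input first",
          d[1], d[2], f)
  }
  K <- as.integer(prod(d) / (d[1] * d[2]))
  out <- cpp_avgpool(x, d[1], d[2], K, as.integer(f))
  dim(out) <- c(d[1] %/% f, d[2] %/% f, d[-(1:2)])
  out
}

avgpool_bwd <- function(dout, f, in_dim) {
  d <- in_dim
  out <- cpp_upsample(dout, d[1] %/% f, d[2] %/% f,
                      as.integer(prod(d) / (d[1] * d[2])), as.integer(f), 1 / f^2)
  dim(out) <- d
  out
}

# adjoint of avgpool_fwd: each value spread uniformly over its s x s block
upsample_rep <- function(x, s) {
  d <- dim(x)
  out <- cpp_upsample(x, d[1], d[2], as.integer(prod(d) / (d[1] * d[2])),
                      as.integer(s), 1 / s^2)
  dim(out) <- c(d[1] * s, d[2] * s, d[-(1:2)])
  out
}

# mean over the orientation axis of [H, W, O, C(, B)]
project_fwd <- function(x) {
  d <- dim(x)
  K <- as.integer(prod(d) / (d[1] * d[2] * d[3]))
  out <- cpp_project_fwd(x, as.integer(d[1] * d[2]), d[3], K)
  dim(out) <- c(d[1], d[2], d[-(1:3)])
  out
}

project_bwd <- function(dout, in_dim) {
  d <- in_dim
  K <- as.integer(prod(d) / (d[1] * d[2] * d[3]))
  dx <- cpp_project_bwd(dout, as.integer(d[1] * d[2]), d[3], K)
  dim(dx) <- d
  dx
}

# channel-wise bias add (channel = second-to-last axis), single fused pass
add_chan_bias <- function(x, bias) {
  d <- dim(x)
  nd <- length(d)
  C <- d[nd - 1L]; B <- d[nd]
  out <- cpp_affine_chan(x, as.integer(prod(d) / (C * B)), C, B,
                         rep(1, C), bias)
  dim(out) <- d
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- user-facing kernel containers -----------------------------------------

#' Construct a spatial (planar) convolution kernel
#'
#' @param weights array `[kh, kw, Cin, Cout]` with odd spatial support.
#' @param bias optional numeric vector of length `Cout`.
#' @export
spatial_kernel <- function(weights, bias = NULL) {
  d <- dim(weights)
  if (length(d) != 4) stopf("spatial kernel weights must be [kh, kw, Cin, Cout]")
  if (d[1] %% 2 == 0 || d[2] %% 2 == 0) stopf("kernel support must be odd")
  if (!is.null(bias) && length(bias) != d[4]) stopf("bias length must equal Cout")
  structure(list(weights = weights, bias = bias), class = "modse2_spatial_kernel")
}

#' Construct an SE(2) group convolution kernel
#'
#' @param weights array `[kh, kw, O, Cin, Cout]` with odd spatial support.
#' @param bias optional numeric vector of length `Cout`.
#' @export
group_kernel <- function(weights, bias = NULL) {
  d <- dim(weights)
  if (length(d) != 5) stopf("group kernel weights must be [kh, kw, O, Cin, Cout]")
  if (d[1] %% 2 == 0 || d[2] %% 2 == 0) stopf("kernel support must be odd")
  if (!is.null(bias) && length(bias) != d[5]) stopf("bias length must equal Cout")
  structure(list(weights = weights, bias = bias), class = "modse2_group_kernel")
}

#' Construct squeeze-and-excitation weights
#'
#' @param w1 matrix `[C, Ch]` (squeeze-to-hidden).
#' @param w2 matrix `[Ch, C]` (hidden-to-gate).
#' @param b1,b2 optional biases (default zero).
#' @export
se_weights <- function(w1, w2, b1 = NULL, b2 = NULL) {
  if (ncol(w1) != nrow(w2) || nrow(w1) != ncol(w2)) {
    stopf("SE weight shapes must be [C, Ch] and [Ch, C]")
  }
  structure(list(w1 = w1, w2 = w2,
                 b1 = b1 %||% numeric(ncol(w1)),
                 b2 = b2 %||% numeric(nrow(w1))),
            class = "modse2_se_weights")
}

# --- user-facing single-sample operations ----------------------------------

as_planar_batch <- function(img) {
  d <- dim(img)
  if (is.null(d)) stopf("image must be a matrix or [H, W, C] array")
  if (length(d) == 2) d <- c(d, 1L)
  array(img, c(d, 1L))
}

#' Lifting convolution: lift a planar image onto the SE(2) orientation grid
#'
#' Correlates the input with `O` rotated copies of one base filter, producing
#' an `[H', W', O, Cout]` orientation feature map: slice `k` is the
#' cross-correlation of the image with [rotate_kernel()]`(psi, k, O)`.
#'
#' @param img `[H, W, C]` image (or `[H, W]` matrix).
#' @param kern a [spatial_kernel()] with `Cin` matching the image channels.
#' @param O orientation count.
#' @param stride positive integer stride.
#' @param padding `"same"` or `"valid"`.
#' @return an `[H', W', O, Cout]` array.
#' @export
lifting_conv <- function(img, kern, O, stride = 1L, padding = "same") {
  x <- as_planar_batch(img)
  d <- dim(kern$weights)
  if (dim(x)[3] != d[3]) {
    stopf("image has %d channels but kernel expects %d", dim(x)[3], d[3])
  }
  Wall <- lifting_bank(kern$weights, O)
  cf <- conv_forward(x, Wall, stride, padding, d[1], d[2])
  out <- unfold_o(cf$out, O)[, , , , 1, drop = FALSE]
  dim(out) <- dim(out)[1:4]
  if (!is.null(kern$bias)) out <- sweep(out, 4, kern$bias, `+`)
  out
}

#' SE(2) group convolution
#'
#' Convolution on orientation feature maps: output at orientation `k` is the
#' cross-correlation of the full `[H, W, O, Cin]` input with
#' [rotate_group_kernel()]`(psi, k)`, coupling a spatial rotation of the
#' kernel with a cyclic shift of its orientation axis.  Equivariant to
#' roto-translations in the same sense as the lifting layer.
#'
#' @param f `[H, W, O, Cin]` orientation feature map.
#' @param kern a [group_kernel()] with matching `O` and `Cin`.
#' @param stride,padding as in [lifting_conv()].
#' @param orientation_shift internal mutation switch; keep `TRUE`.
#' @return an `[H', W', O, Cout]` array.
#' @export
group_conv <- function(f, kern, stride = 1L, padding = "same",
                       orientation_shift = TRUE) {
  d <- dim(kern$weights)
  fd <- dim(f)
  if (length(fd) != 4) stopf("f must be [H, W, O, C]")
  if (fd[3] != d[3]) stopf("orientation mismatch: f has O=%d, kernel O=%d", fd[3], d[3])
  if (fd[4] != d[4]) stopf("channel mismatch: f has C=%d, kernel Cin=%d", fd[4], d[4])
  x <- fold_o(array(f, c(fd, 1L)))
  Wall <- group_bank(kern$weights, orientation_shift)
  cf <- conv_forward(x, Wall, stride, padding, d[1], d[2])
  out <- unfold_o(cf$out, d[3])
  dim(out) <- dim(out)[1:4]
  if (!is.null(kern$bias)) out <- sweep(out, 4, kern$bias, `+`)
  out
}

#' SE(2) group deconvolution (transposed group convolution)
#'
#' The exact linear adjoint of [group_conv()] with the same kernel, stride
#' and padding: `<group_conv(f, kern), h> == <f, group_deconv(h, kern)>` for
#' all `f`, `h`.  With stride 2 it doubles the spatial extent, reconstructing
#' features jointly in the spatial and orientation dimensions; the decoder of
#' the segmentation network is built from these.
#'
#' @param f `[H, W, O, Cout]` feature map in the output space of the paired
#'   group convolution.
#' @param kern a [group_kernel()] `[kh, kw, O, Cin, Cout]`; the result has
#'   `Cin` channels.
#' @param stride,padding as for the paired convolution.
#' @return an `[H*stride, W*stride, O, Cin]` array (for `"same"` padding).
#' @export
group_deconv <- function(f, kern, stride = 1L, padding = "same") {
  d <- dim(kern$weights)
  fd <- dim(f)
  if (length(fd) != 4) stopf("f must be [H, W, O, C]")
  if (fd[3] != d[3]) stopf("orientation mismatch: f has O=%d, kernel O=%d", fd[3], d[3])
  if (fd[4] != d[5]) stopf("channel mismatch: f has C=%d, kernel Cout=%d", fd[4], d[5])
  out_extent <- if (padding == "same") c(fd[1] * stride, fd[2] * stride)
                else c((fd[1] - 1) * stride + d[1], (fd[2] - 1) * stride + d[2])
  x <- fold_o(array(f, c(fd, 1L)))
  Wall <- group_bank(kern$weights)
  df <- deconv_forward(x, Wall, stride, padding, d[1], d[2], out_extent)
  out <- unfold_o(df$out, d[3])
  dim(out) <- dim(out)[1:4]
  if (!is.null(kern$bias)) out <- sweep(out, 4, kern$bias, `+`)
  out
}

#' Spatial average pooling of an orientation feature map
#'
#' Non-overlapping `factor x factor` block means, taken independently per
#' orientation and channel.  Non-divisible extents are an error (silent
#' padding would break the exact-equivariance guarantees).
#'
#' @param f `[H, W, O, C]` array (planar `[H, W, C]` also accepted).
#' @param factor integer pooling factor.
#' @export
spatial_avg_pool <- function(f, factor) {
  avgpool_fwd(f, as.integer(factor))
}

#' Orientation projection (group pooling)
#'
#' Mean over the orientation axis; the output is exactly invariant under
#' cyclic orientation shifts of the input, which is the mechanism by which
#' the classification head becomes rotation invariant.
#'
#' @param f `[H, W, O, C]` array.
#' @param mode only `"mean"` is provided.
#' @return an `[H, W, C]` array.
#' @export
orientation_project <- function(f, mode = "mean") {
  mode <- match.arg(mode, "mean")
  if (length(dim(f)) != 4) stopf("f must be [H, W, O, C]")
  project_fwd(f)
}

#' Squeeze-and-excitation recalibration on the SE(2) group
#'
#' Squeezes by the mean over the spatial AND orientation axes (one statistic
#' per channel), gates through a two-layer bottleneck with sigmoid output,
#' and rescales each channel.  Because the squeeze pools over orientations,
#' the block commutes exactly with roto-translation actions.
#'
#' @param f `[H, W, O, C]` array.
#' @param w an [se_weights()] object with `C` matching `f`.
#' @return the recalibrated feature map, same shape.
#' @export
se_recalibrate <- function(f, w) {
  d <- dim(f)
  if (length(d) != 4) stopf("f must be [H, W, O, C]")
  if (nrow(w$w1) != d[4]) stopf("channel mismatch: f has C=%d, weights expect %d", d[4], nrow(w$w1))
  z <- colMeans(matrix(f, d[1] * d[2] * d[3], d[4]))
  h <- pmax(as.vector(crossprod(w$w1, z)) + w$b1, 0)
  s <- sigmoid(as.vector(crossprod(w$w2, h)) + w$b2)
  sweep(f, 4, s, `*`)
}

#' Normalization statistics container for equivariant batch norm
#'
#' @param mean,var per-channel running statistics (variance must be >= 0).
#' @param gamma,beta per-channel affine parameters.
#' @param eps numerical floor added to the variance.
#' @export
norm_stats <- function(mean, var, gamma = NULL, beta = NULL, eps = 1e-5) {
  C <- length(mean)
  if (length(var) != C) stopf("mean and var must have equal length")
  if (any(var < 0)) stopf("negative variance in supplied statistics")
  if (eps <= 0) stopf("eps must be > 0")
  list(mean = mean, var = var,
       gamma = gamma %||% rep(1, C), beta = beta %||% rep(0, C), eps = eps)
}

#' Orientation-shared batch normalization
#'
#' Per-channel normalization with statistics pooled over the spatial AND
#' orientation axes (a single statistic per channel), followed by the usual
#' affine transform.  Sharing statistics and affine parameters across
#' orientations is what preserves equivariance.
#'
#' @param f `[H, W, O, C]` array.
#' @param stats a [norm_stats()] object (running statistics, used in eval
#'   mode; the affine parameters are used in both modes).
#' @param mode `"train"` (statistics from `f` itself) or `"eval"`.
#' @return the normalized feature map, same shape.
#' @export
equivariant_batch_norm <- function(f, stats, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  d <- dim(f)
  if (length(d) != 4) stopf("f must be [H, W, O, C]")
  if (length(stats$mean) != d[4]) stopf("stats channel count mismatch")
  xm <- matrix(f, d[1] * d[2] * d[3], d[4])
  if (mode == "train") {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
  } else {
    mu <- stats$mean; v <- stats$var
  }
  xhat <- sweep(sweep(xm, 2, mu, `-`), 2, sqrt(v + stats$eps), `/`)
  out <- sweep(sweep(xhat, 2, stats$gamma, `*`), 2, stats$beta, `+`)
  array(out, d)
}

# ===========================================================================
# Internal batched layer framework
# ===========================================================================

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# Orbit-expansion matrix tying 3x3 taps over C4 rotation orbits
# (center / edge / corner), used by the symmetric stem convolution.
sym3_expansion <- function() {
  orbit <- matrix(c(3, 2, 3,
                    2, 1, 2,
                    3, 2, 3), 3, 3)
  E <- matrix(0, 9, 3)
  E[cbind(seq_len(9), as.vector(orbit))] <- 1
  E
}

init_layer <- function(type, ...) {
  a <- list(...)
  ly <- c(list(type = type), a)
  ly$params <- switch(
    type,
    conv = {
      fan <- a$kh * a$kw * a$Cin
      p <- list(w = he_init(c(a$kh, a$kw, a$Cin, a$Cout), fan))
      if (isTRUE(a$bias)) p$b <- numeric(a$Cout)
      p
    },
    symconv = {
      p <- list(wsym = he_init(c(3, a$Cin, a$Cout), 9 * a$Cin))
      if (isTRUE(a$bias)) p$b <- numeric(a$Cout)
      p
    },
    lifting = {
      fan <- a$kh * a$kw * a$Cin
      p <- list(w = he_init(c(a$kh, a$kw, a$Cin, a$Cout), fan))
      if (isTRUE(a$bias)) p$b <- numeric(a$Cout)
      p
    },
    gconv = {
      fan <- a$kh * a$kw * a$O * a$Cin
      p <- list(w = he_init(c(a$kh, a$kw, a$O, a$Cin, a$Cout), fan))
      if (isTRUE(a$bias)) p$b <- numeric(a$Cout)
      p
    },
    gdeconv = {
      # weights are the paired convolution's kernel [kh, kw, O, Cup, Cdown];
      # the deconv maps Cdown -> Cup while upsampling
      fan <- a$kh * a$kw * a$O * a$Cdown
      p <- list(w = he_init(c(a$kh, a$kw, a$O, a$Cup, a$Cdown), fan))
      if (isTRUE(a$bias)) p$b <- numeric(a$Cup)
      p
    },
    bn = {
      n <- if (isTRUE(a$per_orientation)) a$O * a$C else a$C
      list(gamma = rep(1, n), beta = numeric(n))
    },
    se = {
      C <- if (isTRUE(a$flat)) a$O * a$C else a$C
      Ch <- max(1L, ceiling(C / a$r))
      list(w1 = he_init(c(C, Ch), C), b1 = numeric(Ch),
           w2 = he_init(c(Ch, C), Ch), b2 = numeric(C))
    },
    fc = {
      list(w = he_init(c(a$Cin, a$Cout), a$Cin), b = numeric(a$Cout))
    },
    list()
  )
  if (type == "bn") {
    n <- length(ly$params$gamma)
    ly$state <- list(running_mean = numeric(n), running_var = rep(1, n))
    ly$momentum <- a$momentum %||% 0.1
    ly$eps <- a$eps %||% 1e-5
  }
  ly
}

# Batch-norm channel view without transposition: the array layout
# [H, W, O, C, B] keeps everything left of the channel axis contiguous, so a
# plain dim change gives a [nspat, nchan * B] matrix whose column blocks of
# size nchan share one image; per-channel statistics combine the B column
# means.  per_orientation folds (O, C) into the channel axis instead.
bn_channel_view <- function(x, per_orientation) {
  d <- dim(x)
  nd <- length(d)
  if (nd == 5) {
    nchan <- if (per_orientation) d[3] * d[4] else d[4]
  } else if (nd == 4) {
    nchan <- d[3]
  } else stopf("batch norm expects a 4-D or 5-D batch")
  B <- d[nd]
  nspat <- as.integer(prod(d) / (nchan * B))
  xm <- x
  dim(xm) <- c(nspat, nchan * B)
  list(xm = xm, nchan = nchan, B = B, nspat = nspat, d = d)
}

# total over every axis except the channel axis (assumed to sit right
# before the trailing batch axis), used for bias gradients
sum_over_channel <- function(x, nchan) {
  d <- dim(x)
  B <- d[length(d)]
  m <- x
  dim(m) <- c(as.integer(prod(d) / (nchan * B)), nchan * B)
  rowSums(matrix(colSums(m), nchan, B))
}

# per-channel statistic from per-(channel, image) column sums
bn_pool_cols <- function(colstat, nchan, B) {
  if (B == 1L) colstat else rowMeans(matrix(colstat, nchan, B))
}

# expand a per-channel vector to the [nspat, nchan*B] column layout
bn_expand <- function(v, view) {
  rep(rep(v, times = view$B), each = view$nspat)
}

layer_forward <- function(ly, x, training = FALSE) {
  switch(
    ly$type,
    conv = {
      Wmat <- matrix(ly$params$w, ly$kh * ly$kw * ly$Cin, ly$Cout)
      cf <- conv_forward(x, Wmat, ly$stride %||% 1L, ly$padding %||% "same", ly$kh, ly$kw)
      out <- cf$out
      if (!is.null(ly$params$b)) out <- add_chan_bias(out, ly$params$b)
      list(out = out, cache = list(cf = cf))
    },
    symconv = {
      E <- sym3_expansion()
      wfull <- E %*% matrix(ly$params$wsym, 3)
      Wmat <- matrix(array(wfull, c(9, ly$Cin, ly$Cout)), 9 * ly$Cin, ly$Cout)
      cf <- conv_forward(x, Wmat, 1L, "same", 3L, 3L)
      out <- cf$out
      if (!is.null(ly$params$b)) out <- add_chan_bias(out, ly$params$b)
      list(out = out, cache = list(cf = cf))
    },
    lifting = {
      Wall <- lifting_bank(ly$params$w, ly$O)
      cf <- conv_forward(x, Wall, ly$stride %||% 1L, ly$padding %||% "same", ly$kh, ly$kw)
      out <- unfold_o(cf$out, ly$O)
      if (!is.null(ly$params$b)) out <- add_chan_bias(out, ly$params$b)
      list(out = out, cache = list(cf = cf))
    },
    gconv = {
      Wall <- group_bank(ly$params$w, ly$orientation_shift %||% TRUE)
      cf <- conv_forward(fold_o(x), Wall, ly$stride %||% 1L, ly$padding %||% "same",
                         ly$kh, ly$kw)
      out <- unfold_o(cf$out, ly$O)
      if (!is.null(ly$params$b)) out <- add_chan_bias(out, ly$params$b)
      list(out = out, cache = list(cf = cf))
    },
    gdeconv = {
      # exact adjoint of an encoder stage (group conv then average pool):
      # uniform block upsampling (the pool adjoint) composed with a stride-1
      # transposed group convolution.  Keeping the upsampling block-uniform
      # preserves exact 90-degree equivariance on even grids, which a
      # strided transpose cannot (its sampling lattice is not symmetric
      # about the image center).  For 1x1 kernels the channel mixing
      # commutes with the upsampling and is done first, at low resolution.
      s <- ly$stride %||% 2L
      Wall <- group_bank(ly$params$w)
      if (ly$kh == 1L && ly$kw == 1L) {
        d <- dim(x)
        df <- deconv_forward(fold_o(x), Wall, 1L, "same", 1L, 1L,
                             c(d[1], d[2]))
        out <- unfold_o(upsample_rep(df$out, s), ly$O)
      } else {
        ux <- upsample_rep(x, s)
        d <- dim(ux)
        df <- deconv_forward(fold_o(ux), Wall, 1L, "same", ly$kh, ly$kw,
                             c(d[1], d[2]))
        out <- unfold_o(df$out, ly$O)
      }
      if (!is.null(ly$params$b)) out <- add_chan_bias(out, ly$params$b)
      list(out = out, cache = list(df = df, s = s))
    },
    pool = {
      list(out = avgpool_fwd(x, ly$factor), cache = list(in_dim = dim(x)))
    },
    project = {
      list(out = project_fwd(x), cache = list(in_dim = dim(x)))
    },
    gap = {
      d <- dim(x)
      m <- matrix(x, d[1] * d[2])
      out <- matrix(colMeans(m), d[3], d[4])
      list(out = out, cache = list(in_dim = d))
    },
    relu = {
      out <- cpp_relu(x)
      dim(out) <- dim(x)
      list(out = out, cache = list(out = out))
    },
    sigmoid = {
      out <- sigmoid(x)
      list(out = out, cache = list(out = out))
    },
    dropout = {
      if (training && ly$p > 0) {
        mask <- array((runif(length(x)) >= ly$p) / (1 - ly$p), dim(x))
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    bn = {
      po <- isTRUE(ly$per_orientation)
      v <- bn_channel_view(x, po)
      n <- v$nspat * v$B
      if (training) {
        s <- cpp_chan_sums2(v$xm, v$xm, v$nspat, v$nchan, v$B)
        mu <- s[1, ] / n
        va <- s[2, ] / n - mu^2
        state <- list(
          running_mean = (1 - ly$momentum) * ly$state$running_mean + ly$momentum * mu,
          running_var = (1 - ly$momentum) * ly$state$running_var + ly$momentum * va)
      } else {
        mu <- ly$state$running_mean
        va <- ly$state$running_var
        state <- ly$state
      }
      inv_sd <- 1 / sqrt(va + ly$eps)
      xhat <- cpp_affine_chan(v$xm, v$nspat, v$nchan, v$B, inv_sd, -mu * inv_sd)
      ym <- cpp_affine_chan(xhat, v$nspat, v$nchan, v$B,
                            ly$params$gamma, ly$params$beta)
      dim(ym) <- v$d
      list(out = ym,
           cache = list(view = v, xhat = xhat, inv_sd = inv_sd,
                        training = training, mu = mu, va = va),
           state = state)
    },
    se = {
      d <- dim(x)
      flat <- isTRUE(ly$flat)
      # squeeze channel: (O, C) folded for the broken spatial-only variant
      C <- if (flat) d[3] * d[4] else d[4]
      B <- d[length(d)]
      nspat <- as.integer(prod(d) / (C * B))
      z <- matrix(cpp_chan_sums2(x, x, nspat, C * B, 1L)[1, ] / nspat, C, B)
      h <- pmax(crossprod(ly$params$w1, z) + ly$params$b1, 0)
      s <- sigmoid(crossprod(ly$params$w2, h) + ly$params$b2)
      out <- cpp_scale_cols(x, nspat, C * B, as.vector(s), numeric(C * B))
      dim(out) <- d
      list(out = out, cache = list(x = x, z = z, h = h, s = s, nspat = nspat,
                                   C = C, B = B, flat = flat))
    },
    fc = {
      out <- crossprod(ly$params$w, x) + ly$params$b
      list(out = out, cache = list(x = x))
    },
    stopf("unknown layer type '%s'", ly$type)
  )
}

layer_backward <- function(ly, cache, dout) {
  switch(
    ly$type,
    conv = {
      Wmat <- matrix(ly$params$w, ly$kh * ly$kw * ly$Cin, ly$Cout)
      cb <- conv_backward(cache$cf, Wmat, dout, ly$stride %||% 1L, ly$kh, ly$kw)
      g <- list(w = array(cb$dW, dim(ly$params$w)))
      if (!is.null(ly$params$b)) g$b <- sum_over_channel(dout, ly$Cout)
      list(dx = cb$dx, grads = g)
    },
    symconv = {
      E <- sym3_expansion()
      wfull <- E %*% matrix(ly$params$wsym, 3)
      Wmat <- matrix(array(wfull, c(9, ly$Cin, ly$Cout)), 9 * ly$Cin, ly$Cout)
      cb <- conv_backward(cache$cf, Wmat, dout, 1L, 3L, 3L)
      dwfull <- matrix(array(cb$dW, c(9, ly$Cin * ly$Cout)), 9)
      g <- list(wsym = array(crossprod(E, dwfull), c(3, ly$Cin, ly$Cout)))
      if (!is.null(ly$params$b)) g$b <- sum_over_channel(dout, ly$Cout)
      list(dx = cb$dx, grads = g)
    },
    lifting = {
      if (!is.null(ly$params$b)) db <- sum_over_channel(dout, dim(dout)[4])
      Wall <- lifting_bank(ly$params$w, ly$O)
      cb <- conv_backward(cache$cf, Wall, fold_o(dout), ly$stride %||% 1L, ly$kh, ly$kw)
      g <- list(w = lifting_bank_grad(cb$dW, dim(ly$params$w), ly$O))
      if (!is.null(ly$params$b)) g$b <- db
      list(dx = cb$dx, grads = g)
    },
    gconv = {
      os <- ly$orientation_shift %||% TRUE
      if (!is.null(ly$params$b)) db <- sum_over_channel(dout, dim(dout)[4])
      Wall <- group_bank(ly$params$w, os)
      cb <- conv_backward(cache$cf, Wall, fold_o(dout), ly$stride %||% 1L, ly$kh, ly$kw)
      g <- list(w = group_bank_grad(cb$dW, dim(ly$params$w), os))
      if (!is.null(ly$params$b)) g$b <- db
      list(dx = unfold_o(cb$dx, ly$O), grads = g)
    },
    gdeconv = {
      if (!is.null(ly$params$b)) db <- sum_over_channel(dout, dim(dout)[4])
      Wall <- group_bank(ly$params$w)
      if (ly$kh == 1L && ly$kw == 1L) {
        dlow <- avgpool_fwd(fold_o(dout), cache$s)
        cb <- deconv_backward(cache$df, Wall, dlow, 1L, 1L, 1L)
        dx <- unfold_o(cb$dx, ly$O)
      } else {
        cb <- deconv_backward(cache$df, Wall, fold_o(dout), 1L, ly$kh, ly$kw)
        dx <- avgpool_fwd(unfold_o(cb$dx, ly$O), cache$s)
      }
      g <- list(w = group_bank_grad(cb$dW, dim(ly$params$w)))
      if (!is.null(ly$params$b)) g$b <- db
      list(dx = dx, grads = g)
    },
    pool = {
      list(dx = avgpool_bwd(dout, ly$factor, cache$in_dim), grads = list())
    },
    project = {
      list(dx = project_bwd(dout, cache$in_dim), grads = list())
    },
    gap = {
      d <- cache$in_dim
      dx <- array(rep(as.vector(dout), each = d[1] * d[2]) / (d[1] * d[2]), d)
      list(dx = dx, grads = list())
    },
    relu = {
      dx <- cpp_relu_bwd(dout, cache$out)
      dim(dx) <- dim(dout)
      list(dx = dx, grads = list())
    },
    sigmoid = {
      list(dx = dout * cache$out * (1 - cache$out), grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask, grads = list())
    },
    bn = {
      v <- cache$view
      n <- v$nspat * v$B
      s <- cpp_chan_sums2(dout, cache$xhat, v$nspat, v$nchan, v$B)
      dbeta <- s[1, ]
      dgamma <- s[2, ]
      gam <- ly$params$gamma
      if (cache$training) {
        m1 <- gam * dbeta / n      # mean of dxhat per channel
        m2 <- gam * dgamma / n     # mean of dxhat * xhat per channel
        dxm <- cpp_bn_backward(dout, cache$xhat, v$nspat, v$nchan, v$B,
                               gam * cache$inv_sd, m1 * cache$inv_sd,
                               m2 * cache$inv_sd)
      } else {
        dxm <- cpp_affine_chan(dout, v$nspat, v$nchan, v$B,
                               gam * cache$inv_sd, numeric(v$nchan))
      }
      dim(dxm) <- v$d
      list(dx = dxm, grads = list(gamma = dgamma, beta = dbeta))
    },
    se = {
      x <- cache$x; d <- dim(x)
      nspat <- cache$nspat; C <- cache$C; B <- cache$B
      # gradient of the gates: ds[c,b] = sum over squeezed axes of dout * x
      ds <- matrix(cpp_dot_cols(dout, x, nspat, C * B), C, B)
      dpre2 <- ds * cache$s * (1 - cache$s)
      dw2 <- cache$h %*% t(dpre2)
      db2 <- rowSums(dpre2)
      dh <- (ly$params$w2 %*% dpre2) * (cache$h > 0)
      dw1 <- cache$z %*% t(dh)
      db1 <- rowSums(dh)
      dz <- ly$params$w1 %*% dh
      # dx = dout * gate + broadcast mean gradient, fused per column
      dx <- cpp_scale_cols(dout, nspat, C * B, as.vector(cache$s),
                           as.vector(dz) / nspat)
      dim(dx) <- d
      list(dx = dx, grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
    },
    fc = {
      list(dx = ly$params$w %*% dout,
           grads = list(w = cache$x %*% t(dout), b = rowSums(dout)))
    },
    stopf("unknown layer type '%s'", ly$type)
  )
}
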