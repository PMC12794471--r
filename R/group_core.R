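# Discrete SE(2) group algebra.  A group element g = (k, t) pairs an
# orientation index k (theta_k = 2*pi*k/O, counterclockwise) with a continuous
# translation t = (du, dv) in the centered pixel frame.  Composition follows
# (t, R_a) . (t', R_b) = (R_a t' + t, R_{a+b}); the orientation index adds
# modulo O.

#' Construct a discrete SE(2) group element
#'
#' @param k orientation index, `0 <= k < O`; the rotation angle is
#'   `2*pi*k/O` counterclockwise.
#' @param t translation 2-vector `(du, dv)` in the centered pixel frame
#'   (u rightwards, v upwards).
#' @param O number of discrete orientations (>= 1).
#' @return an object of class `se2_element`.
#' @examples
#' g <- se2_element(1, c(1, 0), O = 4)
#' se2_compose(g, se2_inverse(g))  # identity
#' @export
se2_element <- function(k, t = c(0, 0), O = 8L) {
  O <- as.integer(O)
  if (length(O) != 1 || is.na(O) || O < 1) stopf("O must be a single integer >= 1")
  k <- as.integer(k)
  if (length(k) != 1 || is.na(k) || k < 0 || k >= O) {
    stopf("orientation index k must satisfy 0 <= k < O (got k=%s, O=%d)", k, O)
  }
  t <- as.numeric(t)
  if (length(t) != 2 || any(!is.finite(t))) stopf("t must be a finite 2-vector")
  structure(list(k = k, t = t, O = O), class = "se2_element")
}

#' @export
print.se2_element <- function(x, ...) {
  cat(sprintf("SE(2) element: k=%d/%d (theta=%.1f deg), t=(%.3f, %.3f)\n",
              x$k, x$O, 360 * x$k / x$O, x$t[1], x$t[2]))
  invisible(x)
}

#' Identity element of the discrete SE(2) group
#' @param O number of discrete orientations.
#' @export
se2_identity <- function(O = 8L) se2_element(0L, c(0, 0), O)

se2_angle <- function(g) 2 * pi * g$k / g$O

#' Compose two SE(2) group elements
#'
#' `se2_compose(g, h)` is the element "first apply h, then g":
#' `(k_g + k_h mod O, R_{theta_g} t_h + t_g)`.
#'
#' @param g,h `se2_element`s on the same orientation grid.
#' @return an `se2_element`.
#' @export
se2_compose <- function(g, h) {
  if (g$O != h$O) {
    stopf("incompatible group discretizations: O=%d vs O=%d", g$O, h$O)
  }
  se2_element((g$k + h$k) %% g$O,
              as.vector(rotation_matrix(se2_angle(g)) %*% h$t) + g$t,
              g$O)
}

#' Inverse of an SE(2) group element
#'
#' @param g an `se2_element`.
#' @return the element `h` with `se2_compose(g, h)` equal to the identity:
#'   `(-k mod O, -R_{-theta} t)`.
#' @export
se2_inverse <- function(g) {
  se2_element((-g$k) %% g$O,
              as.vector(-rotation_matrix(-se2_angle(g)) %*% g$t),
              g$O)
}

#' Action of an SE(2) element on a point
#'
#' @param g an `se2_element`.
#' @param p a 2-vector (or 2-column matrix of points) in the centered frame.
#' @return `R_theta p + t`, same shape as `p`.
#' @export
act_on_point <- function(g, p) {
  R <- rotation_matrix(se2_angle(g))
  if (is.matrix(p)) {
    sweep(p %*% t(R), 2, g$t, `+`)
  } else {
    as.vector(R %*% p) + g$t
  }
}

# ---------------------------------------------------------------------------
# Action on images (pullback): (g . I)(p) = I(g^-1 . p), sampled about the
# image center with zero fill outside the domain.

#' Action of an SE(2) element on a planar image
#'
#' Computes `(g . I)(p) = I(g^-1 p)` on the pixel grid, rotating about the
#' image center `((W-1)/2, (H-1)/2)` with zero fill outside the frame.  When
#' the angle is an exact multiple of 90 degrees and the translation is
#' integer, the result is an exact pixel permutation; `"auto"` selects that
#' path and falls back to bilinear interpolation otherwise.
#'
#' @param g an `se2_element`.
#' @param img a `[H, W]` matrix or `[H, W, C]` array.
#' @param interpolation one of `"auto"`, `"nearest"`, `"bilinear"`.
#' @return the transformed image, same shape as `img`.
#' @export
act_on_image <- function(g, img, interpolation = c("auto", "nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  d <- dim(img)
  if (is.null(d)) stopf("img must be a matrix or [H,W,C] array")
  if (any(!is.finite(img))) stopf("img must be finite")
  had_mat <- length(d) == 2
  if (had_mat) img <- array(img, c(d, 1L))
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  # output pixel centered coordinates
  grid <- expand.grid(row = seq_len(H) - 1, col = seq_len(W) - 1)
  u <- grid$col - cx
  v <- cy - grid$row
  # source point q = R_{-theta} (p - t)
  Rinv <- rotation_matrix(-se2_angle(g))
  qu <- Rinv[1, 1] * (u - g$t[1]) + Rinv[1, 2] * (v - g$t[2])
  qv <- Rinv[2, 1] * (u - g$t[1]) + Rinv[2, 2] * (v - g$t[2])
  src_rows <- cy - qv + 1
  src_cols <- cx + qu + 1
  exact <- isTRUE(all.equal(g$t, round(g$t), tolerance = 1e-9)) &&
    abs((4 * g$k / g$O) - round(4 * g$k / g$O)) < 1e-9
  sampler <- switch(interpolation,
                    auto = if (exact) nearest_sample else bilinear_sample,
                    nearest = nearest_sample,
                    bilinear = bilinear_sample)
  out <- array(0, dim(img))
  for (ch in seq_len(C)) {
    out[, , ch] <- matrix(sampler(img[, , ch], src_rows, src_cols), H, W)
  }
  if (had_mat) out[, , 1] else out
}

# ---------------------------------------------------------------------------
# Kernel rotation.  Rotating a small odd-sized kernel is a fixed linear map of
# its spatial taps; we materialise that map as a (kh*kw) x (kh*kw) operator so
# that the backward pass is exactly its transpose.  Operators are cached.

.rot_op_cache <- new.env(parent = emptyenv())

# Linear operator M with vec(rotated) = M %*% vec(kernel); rotation of the
# kernel PATTERN by +theta counterclockwise (value at target tap p is read
# from R_{-theta} p).  Exact permutation matrix for multiples of 90 degrees.
rotation_operator <- function(kh, kw, theta) {
  key <- sprintf("%d_%d_%.12f", kh, kw, theta %% (2 * pi))
  hit <- .rot_op_cache[[key]]
  if (!is.null(hit)) return(hit)
  cy <- (kh - 1) / 2; cx <- (kw - 1) / 2
  n <- kh * kw
  M <- matrix(0, n, n)
  Rinv <- rotation_matrix(-theta)
  for (dj in 0:(kw - 1)) {
    for (di in 0:(kh - 1)) {
      a <- 1 + di + kh * dj
      u <- dj - cx; v <- cy - di
      q <- Rinv %*% c(u, v)
      sc <- snap_int(cx + q[1]); sr <- snap_int(cy - q[2])
      r0 <- floor(sr); c0 <- floor(sc)
      fr <- sr - r0;  fc <- sc - c0
      for (dr in 0:1) {
        for (dc in 0:1) {
          wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
          rr <- r0 + dr; cc <- c0 + dc
          if (wgt > 0 && rr >= 0 && rr < kh && cc >= 0 && cc < kw) {
            M[a, 1 + rr + kh * cc] <- M[a, 1 + rr + kh * cc] + wgt
          }
        }
      }
    }
  }
  assign(key, M, envir = .rot_op_cache)
  M
}

#' Rotate a spatial kernel to one of O discrete orientations
#'
#' Rotates the spatial taps of a kernel by `theta_k = 2*pi*k/O`
#' counterclockwise about the kernel center.  The rotation is an exact tap
#' permutation for multiples of 90 degrees and bilinear interpolation with
#' zero fill otherwise.  Channel axes are untouched.
#'
#' @param kern a kernel array `[kh, kw, ...]` with odd `kh`, `kw`.
#' @param k orientation index.
#' @param O orientation count.
#' @return the rotated kernel, same shape.
#' @export
rotate_kernel <- function(kern, k, O) {
  d <- dim(kern)
  if (is.null(d) || length(d) < 2) stopf("kern must be an array [kh, kw, ...]")
  if (d[1] %% 2 == 0 || d[2] %% 2 == 0) {
    stopf("kernel spatial support must be odd (no well-defined center); got %dx%d", d[1], d[2])
  }
  M <- rotation_operator(d[1], d[2], 2 * pi * k / O)
  out <- M %*% matrix(kern, d[1] * d[2])
  array(out, d)
}

#' Rotate an SE(2) group kernel
#'
#' Applies the group transform used by the SE(2) group convolution at output
#' orientation `k`: every orientation slice is spatially rotated by
#' `theta_k`, and the orientation axis is cyclically shifted by `k`
#' (output slice `m` reads input slice `(m - k) mod O`).  Applying with
#' `k = O` returns the input (exactly for 90-degree grids).
#'
#' @param kern a group kernel `[kh, kw, O, Cin, Cout]`.
#' @param k orientation index.
#' @param orientation_shift internal switch used by the mutation harness;
#'   leave `TRUE` for the actual group transform.
#' @return the transformed kernel, same shape.
#' @export
rotate_group_kernel <- function(kern, k, orientation_shift = TRUE) {
  d <- dim(kern)
  if (is.null(d) || length(d) != 5) stopf("group kernel must be [kh, kw, O, Cin, Cout]")
  O <- d[3]
  M <- rotation_operator(d[1], d[2], 2 * pi * k / O)
  wm <- array(kern, c(d[1] * d[2], O, d[4] * d[5]))
  src <- if (orientation_shift) ((seq_len(O) - 1 - k) %% O) + 1 else seq_len(O)
  out <- array(0, dim(wm))
  for (m in seq_len(O)) out[, m, ] <- M %*% wm[, src[m], ]
  array(out, d)
}

# Adjoint of rotate_group_kernel used by backprop: given the gradient of the
# rotated kernel, accumulate the gradient of the base kernel.
unrotate_group_kernel_grad <- function(dkern, k, orientation_shift = TRUE) {
  d <- dim(dkern)
  O <- d[3]
  M <- rotation_operator(d[1], d[2], 2 * pi * k / O)
  wm <- array(dkern, c(d[1] * d[2], O, d[4] * d[5]))
  src <- if (orientation_shift) ((seq_len(O) - 1 - k) %% O) + 1 else seq_len(O)
  out <- array(0, dim(wm))
  for (m in seq_len(O)) out[, src[m], ] <- out[, src[m], ] + crossprod(M, wm[, m, ])
  array(out, d)
}

# ---------------------------------------------------------------------------
# Group action on orientation feature maps [H, W, O, C]: spatial rotation of
# every slice plus a cyclic shift of the orientation axis by +r (input
# rotation by theta_r shifts the output orientation index by +r).

#' Roto-translate an orientation feature map
#'
#' Applies the SE(2) action induced on `[H, W, O, C]` feature maps: each
#' `(orientation, channel)` slice is moved spatially by the element
#' `(r, t)` and the orientation axis is cyclically shifted by `+r`.
#'
#' @param f a `[H, W, O, C]` array.
#' @param r orientation step (integer, may be negative).
#' @param t translation 2-vector in the centered frame.
#' @param interpolation passed to [act_on_image()].
#' @return the transformed feature map, same shape.
#' @export
act_on_feature_map <- function(f, r, t = c(0, 0),
                               interpolation = c("auto", "nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  d <- dim(f)
  if (length(d) != 4) stopf("feature map must be [H, W, O, C]")
  O <- d[3]
  g <- se2_element(((r %% O) + O) %% O, t, O)
  out <- array(0, d)
  src <- ((seq_len(O) - 1 - r) %% O) + 1
  for (k in seq_len(O)) {
    for (c in seq_len(d[4])) {
      out[, , k, c] <- act_on_image(g, f[, , src[k], c], interpolation)
    }
  }
  out
}

#' Cyclically shift the orientation axis of a feature map
#'
#' @param f a `[H, W, O, C]` array.
#' @param r shift (slice `k` of the result is slice `k - r` of the input).
#' @return the shifted feature map.
#' @export
shift_orientation <- function(f, r) {
  d <- dim(f)
  if (length(d) != 4) stopf("feature map must be [H, W, O, C]")
  O <- d[3]
  src <- ((seq_len(O) - 1 - r) %% O) + 1
  f[, , src, , drop = FALSE]
}
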