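# Shared numerical helpers: rotation matrices, bilinear sampling, small
# assertions.  The coordinate convention used everywhere is a centered frame
# with u = col - cx (rightwards), v = cy - row (upwards), cx = (W-1)/2,
# cy = (H-1)/2, and positive angles counterclockwise in (u, v).

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' 2-D rotation matrix
#'
#' @param theta angle in radians, counterclockwise positive.
#' @return a 2x2 rotation matrix.
#' @export
rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Snap values that are within tol of an integer onto it.  Rotations by exact
# multiples of 90 degrees then sample the pixel grid exactly, so the permuted
# path stays bit-exact.
snap_int <- function(x, tol = 1e-9) {
  r <- round(x)
  ifelse(abs(x - r) < tol, r, x)
}

# Vectorised bilinear sampling of a [H, W] matrix at fractional (row, col)
# positions (1-based).  Out-of-domain taps contribute zero.
bilinear_sample <- function(img, rows, cols) {
  H <- nrow(img); W <- ncol(img)
  rows <- snap_int(rows); cols <- snap_int(cols)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0;   fc <- cols - c0
  val <- numeric(length(rows))
  for (dr in 0:1) {
    for (dc in 0:1) {
      wgt <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      rr <- r0 + dr; cc <- c0 + dc
      ok <- wgt > 0 & rr >= 1 & rr <= H & cc >= 1 & cc <= W
      if (any(ok)) val[ok] <- val[ok] + wgt[ok] * img[cbind(rr[ok], cc[ok])]
    }
  }
  val
}

# Nearest-neighbour sampling with the same conventions.
nearest_sample <- function(img, rows, cols) {
  H <- nrow(img); W <- ncol(img)
  rr <- round(snap_int(rows)); cc <- round(snap_int(cols))
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  val <- numeric(length(rows))
  val[ok] <- img[cbind(rr[ok], cc[ok])]
  val
}

# Bilinear resize of a [H, W] or [H, W, C] image to newH x newW, sampling at
# pixel centers (align-corners convention when the extent changes).
resize_bilinear <- function(img, newH, newW) {
  d <- dim(img)
  if (is.null(d)) stopf("resize_bilinear expects a matrix or [H,W,C] array")
  if (length(d) == 2) img <- array(img, c(d, 1L))
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  rs <- if (newH == 1) rep((H + 1) / 2, 1) else 1 + (seq_len(newH) - 1) * (H - 1) / (newH - 1)
  cs <- if (newW == 1) rep((W + 1) / 2, 1) else 1 + (seq_len(newW) - 1) * (W - 1) / (newW - 1)
  grid <- expand.grid(r = rs, c = cs)
  out <- array(0, c(newH, newW, C))
  for (ch in seq_len(C)) {
    out[, , ch] <- matrix(bilinear_sample(img[, , ch], grid$r, grid$c), newH, newW)
  }
  if (length(d) == 2) out <- out[, , 1] else out
}

# Circular mask: zero outside the inscribed disk, so that image rotations
# permute content without clipping corners.
#' Apply a circular (inscribed-disk) mask to an image
#'
#' Zeroes every pixel outside the disk inscribed in the image rectangle.
#' Rotating a masked image moves no content in or out of the frame, which is
#' what makes exact invariance checks attainable.
#'
#' @param img a `[H, W]` matrix or `[H, W, C]` array.
#' @param radius_frac disk radius as a fraction of the inscribed radius.
#' @return the masked image, same shape.
#' @export
circular_mask <- function(img, radius_frac = 1) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  rad <- radius_frac * (min(H, W) - 1) / 2
  rows <- matrix(seq_len(H) - 1, H, W)
  cols <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  m <- ((rows - cy)^2 + (cols - cx)^2) <= rad^2
  if (length(d) == 2) img * m else sweep(img, c(1, 2), m, `*`)
}

minmax01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] < .Machine$double.eps) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}
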