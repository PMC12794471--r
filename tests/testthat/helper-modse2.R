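# Shared fixtures and independent oracles.  The oracles deliberately avoid
# the package's rotation-operator machinery: kernel rotation is done by
# integer coordinate arithmetic (quarter turns only) and convolutions by
# explicit nested loops over the defining sums.

randn_arr <- function(...) array(rnorm(prod(c(...))), c(...))

tiny_cls_config <- function(O = 4L, extent = 32L, seed = 7L, n_classes = 3L) {
  model_config("cls", n_orientations = O, extent = extent, stem_filters = 3L,
               lifting_filters = 4L, block_channels = c(4L, 6L),
               se_ratio = 2L, fc_width = 16L, n_classes = n_classes,
               seed = seed)
}

tiny_seg_config <- function(O = 4L, extent = 16L, seed = 7L) {
  model_config("seg", n_orientations = O, extent = extent, stem_filters = 3L,
               lifting_filters = 4L, block_channels = c(4L, 6L),
               se_ratio = 2L, seed = seed)
}

# Rotate the spatial taps of a kernel [kh, kw, ...] by q quarter turns CCW,
# by integer coordinate arithmetic: target (u, v) reads source R_{-q*90}(u,v),
# with R_{-90}(u, v) = (v, -u).
oracle_rotate90 <- function(w, q) {
  d <- dim(w)
  kh <- d[1]; kw <- d[2]
  cr <- (kh + 1) / 2; cc <- (kw + 1) / 2
  wm <- array(w, c(kh, kw, prod(d) / (kh * kw)))
  out <- array(0, dim(wm))
  for (r in seq_len(kh)) {
    for (c in seq_len(kw)) {
      u <- c - cc; v <- cr - r
      for (qq in seq_len(q %% 4)) {
        tmp <- u; u <- v; v <- -tmp
      }
      out[r, c, ] <- wm[cr - v, cc + u, ]
    }
  }
  array(out, d)
}

# Lifting convolution by explicit summation: out(x, k) = sum_y img(y) *
# psi_k(y - x), psi_k the kernel rotated by k quarter turns (O = 4 only).
oracle_lifting <- function(img, w, O = 4L) {
  d <- dim(img)
  if (length(d) == 2) img <- array(img, c(d, 1L))
  kd <- dim(w)
  H <- dim(img)[1]; W <- dim(img)[2]
  ch <- (kd[1] + 1) %/% 2; cw <- (kd[2] + 1) %/% 2
  out <- array(0, c(H, W, O, kd[4]))
  for (k in 0:(O - 1)) {
    wk <- oracle_rotate90(w, k)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      for (di in seq_len(kd[1])) for (dj in seq_len(kd[2])) {
        yi <- i + di - ch; yj <- j + dj - cw
        if (yi >= 1 && yi <= H && yj >= 1 && yj <= W) {
          for (ci in seq_len(kd[3])) for (co in seq_len(kd[4])) {
            out[i, j, k + 1, co] <- out[i, j, k + 1, co] +
              img[yi, yj, ci] * wk[di, dj, ci, co]
          }
        }
      }
    }
  }
  out
}

# Group convolution by explicit summation over the defining formula:
# out(x, k) = sum_{y, m, c} f(y, m, c) * psi(R_{-k}(y - x), m - k, c, .)
oracle_group_conv <- function(f, w, O = 4L) {
  fd <- dim(f); kd <- dim(w)
  H <- fd[1]; W <- fd[2]
  ch <- (kd[1] + 1) %/% 2; cw <- (kd[2] + 1) %/% 2
  out <- array(0, c(H, W, O, kd[5]))
  for (k in 0:(O - 1)) {
    # transformed kernel: slice m reads source slice (m - k) mod O, spatially
    # rotated by k quarter turns
    wk <- array(0, kd)
    for (m in 0:(O - 1)) {
      src <- ((m - k) %% O) + 1
      wk[, , m + 1, , ] <- oracle_rotate90(w[, , src, , , drop = FALSE], k)
    }
    for (i in seq_len(H)) for (j in seq_len(W)) {
      for (di in seq_len(kd[1])) for (dj in seq_len(kd[2])) {
        yi <- i + di - ch; yj <- j + dj - cw
        if (yi >= 1 && yi <= H && yj >= 1 && yj <= W) {
          for (m in seq_len(O)) for (ci in seq_len(kd[4])) {
            fv <- f[yi, yj, m, ci]
            if (fv != 0) {
              for (co in seq_len(kd[5])) {
                out[i, j, k + 1, co] <- out[i, j, k + 1, co] +
                  fv * wk[di, dj, m, ci, co]
              }
            }
          }
        }
      }
    }
  }
  out
}

expect_maxabs <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
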