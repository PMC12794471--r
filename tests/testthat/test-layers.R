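# The equivariant layer zoo: contracts, hand-checked values, equivariance
# and adjointness, against independent loop-based oracles where stated.

test_that("lifting convolution: zeros, delta stamping, oracle agreement", {
  kern <- spatial_kernel(randn_arr(3, 3, 1, 2))
  z <- lifting_conv(matrix(0, 8, 8), kern, 4)
  expect_equal(dim(z), c(8L, 8L, 4L, 2L))
  expect_true(all(z == 0))

  # delta image: each orientation slice stamps the correspondingly rotated
  # kernel around the delta location (cross-correlation flips the offsets)
  img <- matrix(0, 9, 9); img[5, 5] <- 1
  out <- lifting_conv(img, kern, 4)
  for (k in 0:3) {
    wk <- oracle_rotate90(kern$weights, k)
    for (co in 1:2) {
      stamp <- out[4:6, 4:6, k + 1, co]
      expect_maxabs(stamp, wk[3:1, 3:1, 1, co], 1e-12)
    }
  }

  set.seed(11)
  img <- matrix(rnorm(64), 8, 8)
  expect_maxabs(lifting_conv(img, kern, 4), oracle_lifting(img, kern$weights),
                1e-10)

  expect_error(lifting_conv(array(runif(128), c(8, 8, 2)), kern, 4), "channels")
  expect_error(lifting_conv(img, kern, 4, stride = 0), "stride")
})

test_that("lifting equivariance: rot90 input = shifted-rotated output, exact", {
  set.seed(12)
  img <- matrix(rnorm(256), 16, 16)
  kern <- spatial_kernel(randn_arr(3, 3, 1, 2))
  lhs <- lifting_conv(act_on_image(se2_element(1, c(0, 0), 4), img), kern, 4)
  rhs <- act_on_feature_map(lifting_conv(img, kern, 4), 1)
  expect_identical(dim(lhs), dim(rhs))
  expect_maxabs(lhs, rhs, 1e-12)
})

test_that("group convolution: degenerate cases and oracle agreement", {
  gk <- group_kernel(randn_arr(3, 3, 4, 2, 3))
  z <- group_conv(array(0, c(8, 8, 4, 2)), gk)
  expect_true(all(z == 0))

  # 1x1 kernel with O = 1 is an ordinary pointwise convolution
  w11 <- randn_arr(1, 1, 1, 3, 2)
  f <- randn_arr(6, 6, 1, 3)
  out <- group_conv(f, group_kernel(w11))
  ref <- array(matrix(f, 36, 3) %*% matrix(w11[1, 1, 1, , ], 3, 2),
               c(6, 6, 1, 2))
  expect_maxabs(out, ref, 1e-12)

  set.seed(13)
  f <- randn_arr(8, 8, 4, 2)
  expect_maxabs(group_conv(f, gk), oracle_group_conv(f, gk$weights), 1e-10)

  expect_error(group_conv(randn_arr(8, 8, 8, 2), gk), "orientation mismatch")
  expect_error(group_conv(randn_arr(8, 8, 4, 5), gk), "channel mismatch")
})

test_that("group convolution equivariance under roto-translation, exact", {
  set.seed(14)
  f <- randn_arr(16, 16, 4, 2)
  for (m in 1:4) for (c in 1:2) f[, , m, c] <- circular_mask(f[, , m, c], 0.6)
  gk <- group_kernel(randn_arr(3, 3, 4, 2, 3))
  lhs <- group_conv(act_on_feature_map(f, 1, c(2, -1)), gk)
  rhs <- act_on_feature_map(group_conv(f, gk), 1, c(2, -1))
  expect_maxabs(lhs, rhs, 1e-12)
})

test_that("group deconvolution is the exact adjoint of group convolution", {
  set.seed(15)
  gk <- group_kernel(randn_arr(3, 3, 4, 2, 3))
  expect_true(all(group_deconv(array(0, c(4, 4, 4, 3)), gk, stride = 2) == 0))

  for (rep in 1:5) {
    f <- randn_arr(8, 8, 4, 2)
    h <- randn_arr(4, 4, 4, 3)
    expect_equal(sum(group_conv(f, gk, stride = 2) * h),
                 sum(f * group_deconv(h, gk, stride = 2)), tolerance = 1e-10)
  }

  # full-matrix adjoint oracle on a small instance: materialise group_conv
  # as a matrix from basis vectors and compare its transpose with
  # group_deconv applied to basis vectors
  gk1 <- group_kernel(randn_arr(3, 3, 2, 1, 1))
  nin <- 4 * 4 * 2; nout <- 2 * 2 * 2
  A <- matrix(0, nout, nin)
  for (i in seq_len(nin)) {
    e <- array(0, c(4, 4, 2, 1)); e[i] <- 1
    A[, i] <- as.vector(group_conv(e, gk1, stride = 2))
  }
  for (j in seq_len(nout)) {
    e <- array(0, c(2, 2, 2, 1)); e[j] <- 1
    expect_maxabs(as.vector(group_deconv(e, gk1, stride = 2)), A[j, ], 1e-12)
  }

  # stride-2 deconv of a single-pixel delta stamps the kernel into the
  # upsampled grid: nonzero support sits around the mapped location
  d <- array(0, c(4, 4, 4, 3)); d[2, 2, 1, 1] <- 1
  up <- group_deconv(d, gk, stride = 2)
  expect_equal(dim(up), c(8L, 8L, 4L, 2L))
  nz <- which(apply(abs(up) > 0, c(1, 2), any), arr.ind = TRUE)
  expect_true(all(nz[, 1] >= 2 & nz[, 1] <= 4 & nz[, 2] >= 2 & nz[, 2] <= 4))
})

test_that("spatial average pooling: block means and orientation neutrality", {
  const <- array(3.5, c(4, 4, 2, 2))
  expect_equal(spatial_avg_pool(const, 2), array(3.5, c(2, 2, 2, 2)))

  m <- array(0, c(4, 4, 1, 1))
  m[, , 1, 1] <- matrix(1:16, 4, 4, byrow = TRUE)
  p <- spatial_avg_pool(m, 2)
  expect_equal(p[, , 1, 1], matrix(c(3.5, 11.5, 5.5, 13.5), 2, 2))

  f <- randn_arr(8, 8, 4, 3)
  expect_equal(spatial_avg_pool(shift_orientation(f, 2), 2),
               shift_orientation(spatial_avg_pool(f, 2), 2))

  expect_error(spatial_avg_pool(randn_arr(6, 6, 4, 1), 4), "divisible")
})

test_that("orientation projection is an exact shift-invariant mean", {
  f <- randn_arr(5, 5, 4, 2)
  f[2, 3, , 1] <- c(1, 2, 3, 4)
  p <- orientation_project(f)
  expect_equal(p[2, 3, 1], 2.5)
  const <- array(1.25, c(4, 4, 6, 1))
  expect_equal(orientation_project(const), array(1.25, c(4, 4, 1)))
  # permutation invariance of the mean; deviations only from the
  # non-associativity of floating-point accumulation
  for (r in 1:3) {
    expect_maxabs(orientation_project(shift_orientation(f, r)),
                  orientation_project(f), 1e-14)
  }
})

test_that("squeeze-excitation: saturation, zero-weight gate, commutation", {
  set.seed(16)
  f <- randn_arr(6, 6, 4, 3)
  # zero weights: sigmoid(0) = 0.5 gates every channel
  w0 <- se_weights(matrix(0, 3, 2), matrix(0, 2, 3))
  expect_maxabs(se_recalibrate(f, w0), f / 2, 1e-12)
  # saturated excitation (huge positive bias): output equals input
  wsat <- se_weights(randn_arr(3, 2), randn_arr(2, 3), b2 = rep(50, 3))
  expect_maxabs(se_recalibrate(f, wsat), f, 1e-10)
  # exact commutation with orientation shifts
  w <- se_weights(randn_arr(3, 2), randn_arr(2, 3), rnorm(2), rnorm(3))
  expect_maxabs(se_recalibrate(shift_orientation(f, 2), w),
                shift_orientation(se_recalibrate(f, w), 2), 1e-12)
  expect_error(se_recalibrate(randn_arr(6, 6, 4, 5), w), "channel mismatch")
})

test_that("equivariant batch norm: identity stats, degenerate input, commutation", {
  f <- randn_arr(6, 6, 4, 3)
  st <- norm_stats(rep(0, 3), rep(1, 3), eps = 1e-12)
  expect_maxabs(equivariant_batch_norm(f, st, "eval"), f, 1e-9)

  const <- array(2, c(4, 4, 4, 2))
  st2 <- norm_stats(rep(0, 2), rep(1, 2))
  out <- equivariant_batch_norm(const, st2, "train")
  expect_maxabs(out, array(0, dim(const)), 1e-9)

  st3 <- norm_stats(rnorm(3), runif(3, 0.5, 2), gamma = runif(3, 0.5, 2),
                    beta = rnorm(3))
  expect_maxabs(equivariant_batch_norm(shift_orientation(f, 1), st3, "train"),
                shift_orientation(equivariant_batch_norm(f, st3, "train"), 1),
                1e-12)
  expect_error(norm_stats(rep(0, 3), c(1, -1, 1)), "negative variance")
})
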