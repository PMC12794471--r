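# The discrete SE(2) algebra: group laws, actions on points and images,
# and kernel rotation.

test_that("composition and inverse match hand-computed values", {
  # R_90 (1,0) = (0,1)
  g <- se2_element(1, c(0, 0), 4)
  h <- se2_element(0, c(1, 0), 4)
  gh <- se2_compose(g, h)
  expect_equal(gh$k, 1L)
  expect_equal(gh$t, c(0, 1), tolerance = 1e-12)

  gi <- se2_inverse(se2_element(1, c(1, 0), 4))
  expect_equal(gi$k, 3L)
  expect_equal(gi$t, c(0, 1), tolerance = 1e-12)

  # identity is neutral; inverse composes to identity; involution
  any_g <- se2_element(3, c(2.5, -1.25), 8)
  expect_equal(se2_compose(se2_identity(8), any_g), any_g)
  gid <- se2_compose(any_g, se2_inverse(any_g))
  expect_equal(gid$k, 0L)
  expect_equal(gid$t, c(0, 0), tolerance = 1e-12)
  ginv2 <- se2_inverse(se2_inverse(any_g))
  expect_equal(ginv2$k, any_g$k)
  expect_equal(ginv2$t, any_g$t, tolerance = 1e-12)

  expect_error(se2_compose(se2_element(1, O = 4), se2_element(1, O = 8)),
               "incompatible")
  expect_error(se2_element(4, O = 4), "0 <= k < O")
})

test_that("group laws hold over random triples for O in {4, 8, 16}", {
  set.seed(42)
  for (O in c(4L, 8L, 16L)) {
    for (rep in 1:34) {
      g <- se2_element(sample(0:(O - 1), 1), runif(2, -5, 5), O)
      h <- se2_element(sample(0:(O - 1), 1), runif(2, -5, 5), O)
      u <- se2_element(sample(0:(O - 1), 1), runif(2, -5, 5), O)
      a <- se2_compose(se2_compose(g, h), u)
      b <- se2_compose(g, se2_compose(h, u))
      expect_equal(a$k, b$k)
      expect_equal(a$t, b$t, tolerance = 1e-9)
      # action homomorphism on points
      p <- runif(2, -3, 3)
      expect_equal(act_on_point(se2_compose(g, h), p),
                   act_on_point(g, act_on_point(h, p)), tolerance = 1e-9)
    }
  }
})

test_that("point action matches hand arithmetic", {
  expect_equal(act_on_point(se2_identity(4), c(0.3, -2)), c(0.3, -2))
  expect_equal(act_on_point(se2_element(0, c(2, 3), 4), c(1, 1)), c(3, 4))
  expect_equal(act_on_point(se2_element(2, c(0, 0), 4), c(1, 0)), c(-1, 0),
               tolerance = 1e-12)
})

test_that("image action: identity, exact 90-degree permutation, round trip", {
  m <- matrix(runif(64), 8, 8)
  expect_identical(act_on_image(se2_identity(4), m), m)

  # 2x2 image: 90-degree CCW rotation is the explicit 4-cycle
  m2 <- matrix(c(1, 2, 3, 4), 2, 2)  # [[1,3],[2,4]] by column fill
  r <- act_on_image(se2_element(1, c(0, 0), 4), m2)
  expect_equal(r, matrix(c(3, 1, 4, 2), 2, 2))
  expect_equal(sum(r), sum(m2))
  # pixel multiset conserved for all quarter turns
  for (k in 0:3) {
    rk <- act_on_image(se2_element(k, c(0, 0), 4), m)
    expect_equal(sort(as.vector(rk)), sort(as.vector(m)))
  }

  # bilinear +45 then -45 round trip on a masked smooth image
  g45 <- se2_element(1, c(0, 0), 8)
  grid <- outer(seq_len(33), seq_len(33),
                function(i, j) sin(i / 8) * cos(j / 10))
  sm <- circular_mask(grid, 0.7)
  back <- act_on_image(se2_inverse(g45), act_on_image(g45, sm, "bilinear"),
                       "bilinear")
  inner <- circular_mask(matrix(1, 33, 33), 0.55) == 1
  expect_lt(max(abs((back - sm)[inner])), 1e-2)

  expect_error(act_on_image(g45, sm, "cubic"))
})

test_that("kernel rotation: fixed points, permutation example, composition", {
  w <- randn_arr(3, 3, 2, 2)
  expect_equal(rotate_kernel(w, 0, 4), w)

  # isotropic Gaussian is rotation invariant: exactly under quarter-turn
  # permutations, to bilinear-interpolation accuracy at 45 degrees
  g <- outer(-2:2, -2:2, function(u, v) exp(-(u^2 + v^2) / 2))
  gk <- array(g, c(5, 5, 1, 1))
  for (k in c(2, 4, 6)) expect_maxabs(rotate_kernel(gk, k, 8), gk, 1e-12)
  for (k in c(1, 3, 5, 7)) expect_maxabs(rotate_kernel(gk, k, 8), gk, 0.1)

  # single 1 at top-center moves to left-center under a quarter turn CCW
  delta <- array(0, c(3, 3, 1, 1)); delta[1, 2, 1, 1] <- 1
  rot <- rotate_kernel(delta, 1, 4)
  expect_equal(rot[2, 1, 1, 1], 1)
  expect_equal(sum(rot), 1)

  expect_error(rotate_kernel(array(0, c(2, 2, 1, 1)), 1, 4), "odd")

  # composition: exact for quarter turns, interpolation-limited for O=8
  expect_identical(rotate_kernel(rotate_kernel(w, 1, 4), 2, 4),
                   rotate_kernel(w, 3, 4))
  smooth <- array(outer(-1:1, -1:1, function(u, v) exp(-(u^2 + v^2))),
                  c(3, 3, 1, 1))
  expect_maxabs(rotate_kernel(rotate_kernel(smooth, 1, 8), 2, 8),
                rotate_kernel(smooth, 3, 8), 2e-2)
})

test_that("group-kernel rotation: cyclic order and hand-checked permutation", {
  w <- randn_arr(3, 3, 4, 2, 2)
  expect_equal(rotate_group_kernel(w, 0), w)
  w4 <- w
  for (i in 1:4) w4 <- rotate_group_kernel(w4, 1)
  expect_identical(w4, w)

  # delta-valued group kernel: value at (top-center, slice m) moves to
  # (left-center, slice m+1) under k = 1
  delta <- array(0, c(3, 3, 4, 1, 1)); delta[1, 2, 2, 1, 1] <- 1
  rot <- rotate_group_kernel(delta, 1)
  expect_equal(rot[2, 1, 3, 1, 1], 1)
  expect_equal(sum(rot), 1)
  # independent integer-arithmetic oracle agrees for every k
  for (k in 0:3) {
    wk <- rotate_group_kernel(w, k)
    ref <- array(0, dim(w))
    for (m in 0:3) ref[, , m + 1, , ] <-
        oracle_rotate90(w[, , ((m - k) %% 4) + 1, , , drop = FALSE], k)
    expect_maxabs(wk, ref, 1e-12)
  }
})

test_that("feature-map action shifts orientations the advertised way", {
  f <- randn_arr(8, 8, 4, 2)
  s <- shift_orientation(f, 1)
  expect_equal(s[, , 2, ], f[, , 1, ])
  expect_equal(shift_orientation(s, -1), f)
  expect_equal(orientation_project(shift_orientation(f, 3)),
               orientation_project(f))
})
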