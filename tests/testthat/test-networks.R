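# Reference architectures: output contracts, invariance/equivariance,
# parameter accounting against independent enumeration, baseline matching,
# heatmaps and checkpoints.

test_that("classifier emits normalized probabilities and is 90-degree invariant", {
  cfg <- tiny_cls_config(n_classes = 5L)
  m <- build_classifier(cfg)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  p <- predict_model(m, x)
  expect_equal(dim(p), c(5L, 3L))
  expect_maxabs(colSums(p), rep(1, 3), 1e-6)

  img <- circular_mask(matrix(runif(1024), 32), 0.9)
  probs <- vapply(0:3, function(q) {
    predict_model(m, act_on_image(se2_element(q, c(0, 0), 4), img))[, 1]
  }, numeric(5))
  expect_lt(max(apply(probs, 1, function(v) diff(range(v)))), 1e-3)
})

test_that("model parameter count equals independent enumeration", {
  cfg <- tiny_cls_config()
  m <- build_classifier(cfg)
  # enumerate by architecture arithmetic, independent of the layer objects
  O <- cfg$n_orientations
  sehid <- function(C) max(1, ceiling(C / cfg$se_ratio))
  expected <- 3 * cfg$in_channels * cfg$stem_filters + cfg$stem_filters +  # C4-tied stem
    3 * 3 * cfg$stem_filters * cfg$lifting_filters + cfg$lifting_filters
  Cin <- cfg$lifting_filters
  for (C in cfg$block_channels) {
    expected <- expected + 3 * 3 * O * Cin * C +      # group kernel, no bias
      2 * C +                                          # BN affine
      C * sehid(C) + sehid(C) + sehid(C) * C + C       # SE bottleneck
    Cin <- C
  }
  expected <- expected + Cin * cfg$fc_width + cfg$fc_width +
    cfg$fc_width * cfg$n_classes + cfg$n_classes
  expect_equal(model_parameter_count(m), expected)
})

test_that("layer parameter formulas match hand arithmetic in both modes", {
  expect_equal(count_layer_parameters(layer_param_spec(3, 3, 3, 32)), 896)
  sp <- layer_param_spec(3, 3, 8, 16, G = 4)
  expect_equal(count_layer_parameters(sp), (3 * 3 * 2) * 4 + 16)  # 88
  expect_equal(count_layer_parameters(sp, "standard-grouped"),
               (3 * 3 * 2) * 16 + 16)
  g1 <- layer_param_spec(5, 5, 6, 12, G = 1)
  expect_equal(count_layer_parameters(g1),
               count_layer_parameters(g1, "standard-grouped"))
  expect_error(layer_param_spec(3, 3, 7, 16, G = 4), "divisible")
})

test_that("baseline CNN matches parameters within 10% and is deterministic", {
  cfg <- tiny_cls_config(seed = 21L)
  m <- build_classifier(cfg)
  b <- build_baseline_cnn(cfg, m)
  pm <- model_parameter_count(m); pb <- model_parameter_count(b)
  expect_lt(abs(pb - pm) / pm, 0.10)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  expect_equal(dim(predict_model(b, x)), dim(predict_model(m, x)))
  # fixed seed => identical initialization and forward outputs
  b2 <- build_baseline_cnn(cfg, build_classifier(cfg))
  expect_identical(predict_model(b, x), predict_model(b2, x))
})

test_that("segmenter: contract, exact equivariance, constant-input symmetry", {
  cfg <- tiny_seg_config()
  m <- build_segmenter(cfg)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  p <- predict_model(m, x)
  expect_equal(dim(p), c(16L, 16L, 1L, 2L))
  expect_true(all(p > 0 & p < 1))

  img <- circular_mask(matrix(runif(256), 16), 0.9)
  g <- se2_element(1, c(0, 0), 4)
  lhs <- predict_model(m, act_on_image(g, img))[, , 1, 1]
  rhs <- act_on_image(g, predict_model(m, img)[, , 1, 1])
  expect_maxabs(lhs, rhs, 1e-3)

  z <- predict_model(m, array(0, c(16, 16, 1, 1)))[, , 1, 1]
  expect_lt(diff(range(z)), 1e-12)
})

test_that("activation heatmap: shape, range, rotation commutation", {
  cfg <- tiny_cls_config()
  m <- build_classifier(cfg)
  img <- circular_mask(matrix(runif(1024), 32), 0.9)
  hm <- activation_heatmap(m, img)
  expect_equal(dim(hm), c(32L, 32L))
  expect_true(all(hm >= 0 & hm <= 1))
  g <- se2_element(1, c(0, 0), 4)
  expect_maxabs(activation_heatmap(m, act_on_image(g, img)),
                act_on_image(g, activation_heatmap(m, img)), 1e-3)
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  cfg <- tiny_cls_config(seed = 31L)
  m <- build_classifier(cfg)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  dir <- tempfile("ckpt")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(predict_model(m2, x), predict_model(m, x))

  # corrupt the stored architecture: shapes no longer match
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  meta$config$block_channels <- c(5L, 6L)
  yaml::write_yaml(meta, file.path(dir, "config.yaml"))
  expect_error(load_model(dir), "mismatched shape")
})
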