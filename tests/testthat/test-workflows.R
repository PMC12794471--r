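# Training/evaluation loops and the verification harness: determinism,
# loss descent, checkpoint round trips, and mutation sensitivity.

small_cls_data <- function(n = 60, seed = 2) {
  spec <- synthetic_spec("cls", n_samples = n, extent = 32, rotate = FALSE,
                         sigma = 0.05, seed = seed,
                         shapes = c("disk", "square", "cross"))
  gen_classification_set(spec)
}

test_that("training is deterministic and decreases the loss on separable data", {
  ds <- small_cls_data()
  cfg <- tiny_cls_config(O = 4L, seed = 1L)
  tc <- train_config("cls", epochs = 4, batch_size = 10, seed = 5)
  f1 <- train_model(build_classifier(cfg), ds, tc)
  f2 <- train_model(build_classifier(cfg), ds, tc)
  expect_identical(f1$record$epoch_loss, f2$record$epoch_loss)
  expect_lt(tail(f1$record$epoch_loss, 1), f1$record$epoch_loss[1])

  expect_error(train_model(build_classifier(cfg), ds, train_config("seg")),
               "does not match")
})

test_that("evaluation: self-consistency, report fields, seg edge case", {
  ds <- small_cls_data(30)
  cfg <- tiny_cls_config(O = 4L, seed = 2L)
  m <- build_classifier(cfg)
  probs <- predict_model(m, ds$x)
  self <- list(task = "cls", x = ds$x, y = apply(probs, 2, which.max))
  ev <- evaluate_model(m, self)
  expect_equal(ev$accuracy, 1)
  expect_true(!is.null(ev$auc))

  # untrained balanced binary problem: accuracy near chance
  set.seed(3)
  n <- 200
  xb <- array(runif(32 * 32 * n), c(32, 32, 1, n))
  yb <- rep(1:2, each = n / 2)
  cfg2 <- tiny_cls_config(O = 4L, seed = 3L, n_classes = 2L)
  acc <- evaluate_model(build_classifier(cfg2),
                        list(task = "cls", x = xb, y = yb))$accuracy
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n) + 0.25)  # loose binomial band

  # all-background segmentation prediction against non-empty truths
  truth <- matrix(0, 8, 8); truth[3:5, 3:5] <- 1
  m0 <- segmentation_metrics(matrix(0, 8, 8), truth)
  expect_equal(m0$dice, 0)
  expect_equal(m0$recall, 0)
})

test_that("segmentation training descends and checkpoints reproduce metrics", {
  spec <- synthetic_spec("seg", n_samples = 24, extent = 16, seed = 4, sigma = 0.05)
  d <- gen_segmentation_set(spec)
  ds <- list(task = "seg", x = d$x, y = d$y)
  cfg <- tiny_seg_config(seed = 5L)
  fit <- train_model(build_segmenter(cfg), ds,
                     train_config("seg", epochs = 4, batch_size = 8, seed = 6))
  expect_lt(tail(fit$record$epoch_loss, 1), fit$record$epoch_loss[1])

  dir <- tempfile("ck")
  save_model(fit$model, dir)
  ev1 <- evaluate_model(fit$model, ds)
  ev2 <- evaluate_model(load_model(dir), ds)
  expect_identical(ev1$dice, ev2$dice)
})

test_that("verification harness passes on the shipped default configuration", {
  v <- verify_equivariance(tolerance = 1e-4)
  expect_true(all(v$pass))
  expect_true(all(c("lifting_equivariance", "groupconv_equivariance",
                    "deconv_adjointness", "endtoend_invariance") %in% v$check))
})

test_that("verification harness detects each shipped broken variant", {
  expected_fail <- list(
    no_orientation_shift = "groupconv_equivariance",
    per_orientation_bn = "bn_commutes_train",
    spatial_se = "se_commutes")
  for (va in names(expected_fail)) {
    v <- verify_equivariance(variant = va)
    expect_false(all(v$pass), info = va)
    bad <- v[v$check == expected_fail[[va]], ]
    expect_false(bad$pass, info = va)
    expect_gt(bad$max_deviation, 10 * bad$tolerance)
  }
})
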