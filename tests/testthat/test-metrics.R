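# Classification/segmentation metrics, ROC/AUC and the training losses:
# hand-checked values, algebraic identities, and rank-statistic cross-checks.

test_that("classification metrics match hand arithmetic and handle edges", {
  y <- c(rep(1, 10), rep(0, 10))
  p <- c(rep(1, 8), 0, 0, rep(0, 8), 1, 1)  # TP=8 FP=2 FN=2 TN=8
  m <- classification_metrics(y, p, positive_class = 1)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)

  perf <- classification_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$f1, 1)

  # all-negative predictions: recall 0, precision undefined
  m0 <- classification_metrics(c(1, 1, 0, 0), c(0, 0, 0, 0), positive_class = 1)
  expect_equal(m0$recall, 0)
  expect_true(is.na(m0$precision))

  expect_error(classification_metrics(1:3, 1:4), "length")
  expect_error(classification_metrics(integer(0), integer(0)), "empty")
})

test_that("segmentation metrics: hand values, conventions, identities", {
  a <- matrix(1, 4, 4)
  expect_equal(segmentation_metrics(a, a)$dice, 1)
  expect_equal(segmentation_metrics(a, a)$iou, 1)

  dj1 <- matrix(0, 4, 4); dj1[1, 1] <- 1
  dj2 <- matrix(0, 4, 4); dj2[4, 4] <- 1
  expect_equal(segmentation_metrics(dj1, dj2)$dice, 0)
  expect_equal(segmentation_metrics(dj1, dj2)$iou, 0)

  # |A| = |B| = 100, overlap 50 -> D = 0.5, IoU = 1/3
  A <- matrix(0, 20, 20); A[1:10, 1:10] <- 1
  B <- matrix(0, 20, 20); B[6:15, 1:10] <- 1
  m <- segmentation_metrics(A, B)
  expect_equal(m$dice, 0.5)
  expect_equal(m$iou, 1 / 3)

  z <- matrix(0, 4, 4)
  expect_equal(segmentation_metrics(z, z)$dice, 1)  # both-empty convention

  expect_error(segmentation_metrics(a, matrix(1, 3, 3)), "shapes")
  expect_error(segmentation_metrics(matrix(0.5, 4, 4), a), "binary")

  # identities on random mask pairs: D = 2 IoU / (1 + IoU), pixel F1 = D,
  # symmetry, precision(A,B) = recall(B,A)
  set.seed(5)
  for (i in 1:100) {
    p <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    t <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    m <- segmentation_metrics(p, t)
    expect_equal(m$dice, 2 * m$iou / (1 + m$iou))
    expect_gte(m$dice, m$iou)
    if (!is.na(m$precision) && !is.na(m$recall) && (m$precision + m$recall) > 0) {
      f1 <- 2 * m$precision * m$recall / (m$precision + m$recall)
      expect_equal(f1, m$dice)
    }
    ms <- segmentation_metrics(t, p)
    expect_equal(ms$dice, m$dice)
    expect_equal(ms$iou, m$iou)
    expect_equal(ms$recall, m$precision)
  }
})

test_that("ROC/AUC: separation, ties, rank-statistic agreement", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  # Mann-Whitney equivalence on random score vectors (with ties)
  set.seed(6)
  for (i in 1:50) {
    y <- rbinom(30, 1, 0.5)
    if (sum(y) == 0 || sum(y) == 30) next
    s <- round(rnorm(30), 1)  # rounding induces ties
    auc <- roc_auc(y, s)$auc
    r <- rank(s)
    mw <- (sum(r[y == 1]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(1 - y))
    expect_equal(auc, mw, tolerance = 1e-9)
  }
})

test_that("cross-entropy loss: closed forms", {
  onehot <- diag(3)
  expect_lt(cross_entropy_loss(diag(3), onehot), 1e-10)
  K <- 4
  unif <- matrix(1 / K, 2, K)
  lab <- matrix(0, 2, K); lab[1, 2] <- 1; lab[2, 4] <- 1
  expect_equal(cross_entropy_loss(unif, lab), log(K), tolerance = 1e-9)
  probs <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  labs <- rbind(c(1, 0), c(0, 1))
  expect_equal(cross_entropy_loss(probs, labs),
               mean(c(log(2), log(4 / 3))), tolerance = 1e-9)
  expect_error(cross_entropy_loss(matrix(0.6, 2, 2), matrix(1, 2, 2)), "sum to 1")
})

test_that("Jaccard loss: complements, hand value, limit to 1 - IoU", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_lt(jaccard_loss(t, t), 1e-9 + 1 - (2 + 1) / (2 + 1))  # eps-limited 0
  expect_gt(jaccard_loss(1 - t, t), 0.5)  # complement, near 1
  # pred all 0.5, truth half-ones on a 2-pixel grid
  p2 <- matrix(c(0.5, 0.5), 1, 2); t2 <- matrix(c(1, 0), 1, 2)
  eps <- 1
  expect_equal(jaccard_loss(p2, t2, smooth = eps), 1 - (0.5 + eps) / (1.5 + eps))
  # as smoothing vanishes and predictions harden, loss -> 1 - IoU
  set.seed(7)
  pb <- matrix(rbinom(64, 1, 0.4), 8, 8)
  tb <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_equal(jaccard_loss(pb, tb, smooth = 1e-12),
               1 - segmentation_metrics(pb, tb)$iou, tolerance = 1e-9)
})

test_that("metrics serialize to flat JSON with null undefined markers", {
  m <- classification_metrics(c(1, 1, 0, 0), c(0, 0, 0, 0), positive_class = 1)
  js <- jsonlite::fromJSON(metrics_to_json(m))
  expect_null(js$precision)
  expect_equal(js$recall, 0)
  f <- tempfile(fileext = ".csv")
  roc_to_csv(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2)), f)
  curve <- read.csv(f)
  expect_named(curve, c("threshold", "fpr", "tpr"))
})
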