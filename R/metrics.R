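# Classification and segmentation metrics, ROC/AUC, and the two training
# losses.  Zero-denominator metrics return NA (an explicit undefined marker,
# serialized as null) rather than 0 or NaN, so aggregation can skip them
# deliberately.

confusion_counts <- function(y_true, y_pred, positive) {
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

metrics_from_counts <- function(cc) {
  acc <- safe_div(cc$TP + cc$TN, cc$TP + cc$TN + cc$FP + cc$FN)
  p <- safe_div(cc$TP, cc$TP + cc$FP)
  r <- safe_div(cc$TP, cc$TP + cc$FN)
  f1 <- if (is.na(p) || is.na(r) || (p + r) == 0) NA_real_ else 2 * p * r / (p + r)
  list(accuracy = acc, precision = p, recall = r, f1 = f1)
}

#' Classification metrics (accuracy, precision, recall, F1)
#'
#' Binary mode (with `positive_class`) reports the four scalars for that
#' class; multi-class mode reports overall accuracy plus per-class
#' one-vs-rest precision/recall/F1 and their unweighted macro averages.
#' Undefined ratios (zero denominators) are returned as `NA`.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param positive_class optional label designating the positive class.
#' @return a `modse2_metrics` list.
#' @export
classification_metrics <- function(y_true, y_pred, positive_class = NULL) {
  if (length(y_true) != length(y_pred)) stopf("label vectors differ in length")
  if (length(y_true) == 0) stopf("empty input")
  if (!is.null(positive_class)) {
    cc <- confusion_counts(y_true, y_pred, positive_class)
    out <- c(metrics_from_counts(cc), list(counts = cc, positive_class = positive_class))
    class(out) <- "modse2_metrics"
    return(out)
  }
  classes <- sort(unique(c(y_true, y_pred)))
  per <- lapply(classes, function(cl) {
    cc <- confusion_counts(y_true, y_pred, cl)
    metrics_from_counts(cc)
  })
  names(per) <- as.character(classes)
  macro <- function(field) {
    v <- vapply(per, function(m) m[[field]], 0)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out <- list(accuracy = mean(y_true == y_pred),
              precision = macro("precision"), recall = macro("recall"),
              f1 = macro("f1"), per_class = per)
  class(out) <- "modse2_metrics"
  out
}

check_binary_mask <- function(m, nm) {
  if (!all(m %in% c(0, 1))) stopf("%s must be strictly binary (0/1)", nm)
}

#' Segmentation overlap metrics (Dice, IoU, pixel precision/recall)
#'
#' `Dice = 2|A n B| / (|A| + |B|)` and `IoU = |A n B| / |A u B|` on binary
#' masks, plus pixel-level precision and recall.  When both masks are empty
#' the overlap scores are 1 by convention (a correct all-background
#' prediction is not penalized); the convention is recorded in the report.
#'
#' @param pred,truth binary `[H, W]` masks of equal shape.
#' @return a `modse2_metrics` list with fields `dice`, `iou`, `precision`,
#'   `recall`, `counts`.
#' @export
segmentation_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stopf("mask shapes differ")
  check_binary_mask(pred, "pred"); check_binary_mask(truth, "truth")
  inter <- sum(pred * truth)
  a <- sum(pred); b <- sum(truth)
  if (a == 0 && b == 0) {
    dice <- 1; iou <- 1
  } else {
    dice <- 2 * inter / (a + b)
    iou <- inter / (a + b - inter)
  }
  out <- list(dice = dice, iou = iou,
              precision = safe_div(inter, a), recall = safe_div(inter, b),
              counts = list(TP = inter, FP = a - inter, FN = b - inter,
                            TN = length(pred) - a - b + inter),
              empty_convention = "both-empty masks score dice = iou = 1")
  class(out) <- "modse2_metrics"
  out
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold, returns the (FPR, TPR) curve
#' and the trapezoid-rule AUC; tied scores collapse onto one operating
#' point, making the trapezoid AUC equal to the rank (Mann-Whitney)
#' statistic with tie correction.
#'
#' @param y_true binary (0/1) labels; both classes must be present.
#' @param scores real-valued scores, higher = more positive.
#' @return `list(curve = data.frame(threshold, fpr, tpr), auc = scalar)`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stopf("length mismatch")
  y <- as.integer(y_true)
  if (!all(y %in% c(0L, 1L))) stopf("labels must be 0/1")
  np <- sum(y == 1L); nn <- sum(y == 0L)
  if (np == 0 || nn == 0) stopf("both classes must be present to form a ROC curve")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / nn, 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  if (curve$fpr[nrow(curve)] < 1) {
    auc <- auc + (1 - curve$fpr[nrow(curve)]) * 1  # terminal segment to (1,1)
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  list(curve = curve, auc = auc)
}

#' Categorical cross-entropy
#'
#' Mean over samples of `-sum_c y_c log(p_c + eps)`.
#'
#' @param probs `[n, K]` matrix of class probabilities (rows sum to 1).
#' @param labels `[n, K]` one-hot matrix.
#' @param eps log clamp (default 1e-12).
#' @export
cross_entropy_loss <- function(probs, labels, eps = 1e-12) {
  if (!identical(dim(probs), dim(labels))) stopf("shape mismatch")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stopf("probability rows must sum to 1")
  mean(-rowSums(labels * log(probs + eps)))
}

#' Soft Jaccard (IoU) loss
#'
#' `1 - (sum(p*t) + eps) / (sum(p) + sum(t) - sum(p*t) + eps)`: the smoothed
#' complement of the intersection-over-union, differentiable in the
#' predicted probabilities and bounded in [0, 1].
#'
#' @param pred_probs predicted probabilities in [0, 1], any shape.
#' @param truth binary mask of the same shape.
#' @param smooth smoothing constant (default 1, for training stability; the
#'   evaluation metrics use the unsmoothed Eq. forms).
#' @export
jaccard_loss <- function(pred_probs, truth, smooth = 1) {
  if (!identical(dim(pred_probs), dim(truth)) &&
      length(pred_probs) != length(truth)) stopf("shape mismatch")
  inter <- sum(pred_probs * truth)
  union <- sum(pred_probs) + sum(truth) - inter
  1 - (inter + smooth) / (union + smooth)
}

#' Serialize a metrics report to JSON
#'
#' Flat snake_case keys; undefined values become `null`.
#'
#' @param metrics a `modse2_metrics` list (or any named list of scalars).
#' @param path optional file to write to.
#' @return the JSON string, invisibly when writing to a file.
#' @export
metrics_to_json <- function(metrics, path = NULL) {
  js <- jsonlite::toJSON(rapply(unclass(metrics), unclass, how = "replace"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write a ROC curve to CSV
#'
#' @param roc result of [roc_auc()].
#' @param path output CSV path (columns threshold, fpr, tpr).
#' @export
roc_to_csv <- function(roc, path) {
  write.csv(roc$curve, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.modse2_metrics <- function(x, ...) {
  flat <- x[vapply(x, function(v) is.numeric(v) && length(v) == 1, TRUE)]
  cat(paste(sprintf("%s: %s", names(flat),
                    vapply(flat, function(v) ifelse(is.na(v), "undefined",
                                                    sprintf("%.4f", v)), "")),
            collapse = "  "), "\n")
  invisible(x)
}
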