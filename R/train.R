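# Training loop: Adam with weight decay, categorical cross-entropy for
# classification and soft-Jaccard loss for segmentation, deterministic under
# a seed.  Gradients come from the hand-written reverse-mode passes of the
# layer framework.

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam, learning rate 0.001,
#' batch size 8 for classification and 32 for segmentation, categorical
#' cross-entropy / Jaccard loss, weight decay 0.0005.  The reference epoch
#' budgets are 100 (classification) and 70 (segmentation); desk-scale runs
#' use far fewer.
#'
#' @param task `"cls"` or `"seg"` (sets batch-size and loss defaults).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training set.
#' @param weight_decay L2 penalty added to weight gradients (biases and
#'   normalization parameters exempt).
#' @param seed RNG seed controlling shuffling, dropout and initialization
#'   downstream.
#' @param early_stop_patience if set, stop when the epoch training loss has
#'   not improved by `early_stop_tol` for this many consecutive epochs.
#' @param early_stop_tol minimum improvement that resets the patience counter.
#' @param refresh_stats recalibrate batch-norm running statistics on the
#'   training set after the last epoch (see [refresh_norm_stats()]).
#' @param verbose print per-epoch losses.
#' @export
train_config <- function(task = c("cls", "seg"), lr = 0.001,
                         batch_size = NULL, epochs = NULL,
                         weight_decay = 5e-4, seed = 1L,
                         early_stop_patience = NULL, early_stop_tol = 1e-3,
                         refresh_stats = TRUE, verbose = FALSE) {
  task <- match.arg(task)
  cfg <- list(task = task, optimizer = "adam", lr = lr,
              batch_size = as.integer(batch_size %||% if (task == "cls") 8L else 32L),
              loss = if (task == "cls") "categorical_crossentropy" else "jaccard",
              epochs = as.integer(epochs %||% if (task == "cls") 100L else 70L),
              weight_decay = weight_decay, seed = as.integer(seed),
              early_stop_patience = early_stop_patience,
              early_stop_tol = early_stop_tol,
              refresh_stats = isTRUE(refresh_stats), verbose = isTRUE(verbose))
  if (cfg$lr <= 0) stopf("learning rate must be > 0")
  if (cfg$batch_size < 1 || cfg$epochs < 1) stopf("batch size and epochs must be >= 1")
  cfg
}

decayed_param <- function(name) name %in% c("w", "wsym", "w1", "w2")

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    lapply(ly$params, function(p) list(m = array(0, dim(p) %||% length(p)),
                                       v = array(0, dim(p) %||% length(p))))
  })
}

adam_step <- function(model, grads, state, t, cfg,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      if (cfg$weight_decay > 0 && decayed_param(pn)) {
        g <- g + cfg$weight_decay * model$layers[[nm]]$params[[pn]]
      }
      st <- state[[nm]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      p <- model$layers[[nm]]$params[[pn]]
      newp <- p - cfg$lr * mh / (sqrt(vh) + eps)
      if (is.null(dim(p))) newp <- as.vector(newp)
      model$layers[[nm]]$params[[pn]] <- newp
      state[[nm]][[pn]] <- st
    }
  }
  list(model = model, state = state)
}

# Loss + gradient at the model output.  Classification models output logits
# (softmax applied here, jointly with the cross-entropy gradient);
# segmentation models output sigmoid probabilities.
loss_and_grad <- function(task, out, target) {
  if (task == "cls") {
    B <- ncol(out)
    probs <- softmax_cols(out)
    idx <- cbind(target, seq_len(B))
    loss <- mean(-log(probs[idx] + 1e-12))
    donehot <- probs
    donehot[idx] <- donehot[idx] - 1
    list(loss = loss, dout = donehot / B)
  } else {
    d <- dim(out)
    B <- d[length(d)]
    eps <- 1
    pm <- matrix(out, ncol = B)
    tm <- matrix(target, ncol = B)
    inter <- colSums(pm * tm)
    uni <- colSums(pm) + colSums(tm) - inter
    loss <- mean(1 - (inter + eps) / (uni + eps))
    dl <- -(sweep(tm, 2, uni + eps, `*`) -
              sweep(1 - tm, 2, inter + eps, `*`)) /
      matrix(rep((uni + eps)^2, each = nrow(pm)), ncol = B) / B
    list(loss = loss, dout = array(dl, d))
  }
}

slice_batch <- function(x, idx) {
  d <- dim(x)
  if (is.null(d)) x[idx] else x[, , , idx, drop = FALSE]
}

#' Recalibrate batch-norm running statistics
#'
#' Replaces every batch-norm layer's running mean and variance with the
#' exact population statistics of its inputs over a dataset, computed with
#' the final weights (one forward pass in training mode, dropout disabled).
#' Exponential moving averages collected during training lag behind the
#' rapidly moving weights; recalibration closes the train/eval gap.
#'
#' @param model a `modse2_model`.
#' @param x input batch array `[H, W, C, N]`.
#' @param batch_size forward batch size.
#' @return the model with refreshed statistics.
#' @export
refresh_norm_stats <- function(model, x, batch_size = 32L) {
  probe <- model
  for (nm in names(probe$layers)) {
    if (probe$layers[[nm]]$type == "dropout") probe$layers[[nm]]$p <- 0
  }
  N <- dim(x)[4]
  sums <- list()
  nb <- 0L
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    fwd <- run_program(probe, x[, , , idx, drop = FALSE], training = TRUE)
    nb <- nb + 1L
    for (i in seq_along(probe$program)) {
      st <- probe$program[[i]]
      if (st$kind == "layer" && probe$layers[[st$layer]]$type == "bn") {
        ch <- fwd$caches[[i]]
        if (is.null(sums[[st$layer]])) sums[[st$layer]] <- list(mu = 0, m2 = 0)
        sums[[st$layer]]$mu <- sums[[st$layer]]$mu + ch$mu
        sums[[st$layer]]$m2 <- sums[[st$layer]]$m2 + ch$mu^2 + ch$va
      }
    }
  }
  for (nm in names(sums)) {
    mu <- sums[[nm]]$mu / nb
    va <- pmax(sums[[nm]]$m2 / nb - mu^2, 0)  # total variance across batches
    model$layers[[nm]]$state <- list(running_mean = mu, running_var = va)
  }
  model
}

#' Train a model
#'
#' Runs Adam over minibatches of a dataset with the configured loss;
#' deterministic given `cfg$seed`.  Batch-norm running statistics are
#' updated during training and used at evaluation.
#'
#' @param model a `modse2_model`.
#' @param data a dataset list with fields `x` (`[H, W, C, N]`), and `y`
#'   (integer class labels for classification, `[H, W, 1, N]` binary masks
#'   for segmentation); see [as_dataset()].
#' @param cfg a [train_config()].
#' @return `list(model, record)` where `record` holds the per-epoch loss
#'   trajectory, the config snapshot and the seed.
#' @export
train_model <- function(model, data, cfg) {
  if (model$task != cfg$task) stopf("model task '%s' does not match training task '%s'",
                                    model$task, cfg$task)
  if (model$task == "cls" && !is.numeric(data$y)) stopf("classification needs integer labels")
  if (model$task == "seg" && is.null(dim(data$y))) stopf("segmentation needs mask arrays")
  N <- dim(data$x)[4]
  if (N < 1) stopf("empty dataset")
  set.seed(cfg$seed)
  opt <- adam_init(model)
  t <- 0L
  epoch_loss <- numeric(0)
  best <- Inf; stall <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    losses <- numeric(0)
    for (start in seq(1, N, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, N)]
      xb <- data$x[, , , idx, drop = FALSE]
      yb <- slice_batch(data$y, idx)
      fwd <- run_program(model, xb, training = TRUE)
      for (nm in names(fwd$states)) model$layers[[nm]]$state <- fwd$states[[nm]]
      lg <- loss_and_grad(model$task, fwd$out, yb)
      bwd <- run_backward(model, fwd, lg$dout)
      t <- t + 1L
      up <- adam_step(model, bwd$grads, opt, t, cfg)
      model <- up$model; opt <- up$state
      losses <- c(losses, lg$loss)
    }
    epoch_loss[ep] <- mean(losses)
    if (cfg$verbose) message(sprintf("epoch %d: loss %.5f", ep, epoch_loss[ep]))
    if (!is.null(cfg$early_stop_patience)) {
      if (epoch_loss[ep] < best - cfg$early_stop_tol) {
        best <- epoch_loss[ep]; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$early_stop_patience) break
      }
    }
  }
  if (isTRUE(cfg$refresh_stats)) {
    model <- refresh_norm_stats(model, data$x, max(cfg$batch_size, 32L))
  }
  list(model = model,
       record = list(epoch_loss = epoch_loss, epochs_run = length(epoch_loss),
                     config = cfg, seed = cfg$seed))
}

#' Evaluate a model on a dataset
#'
#' Classification: accuracy, macro precision/recall/F1 and macro
#' one-vs-rest AUC.  Segmentation: Dice, IoU, pixel precision and recall
#' averaged per image (predictions thresholded at 0.5).
#'
#' @param model a trained `modse2_model`.
#' @param data a dataset list (see [train_model()]).
#' @param batch_size forward batch size.
#' @return a `modse2_metrics` list.
#' @export
evaluate_model <- function(model, data, batch_size = 32L) {
  N <- dim(data$x)[4]
  if (N < 1) stopf("empty dataset")
  if (model$task == "cls") {
    if (!is.numeric(data$y)) stopf("classification model evaluated on non-label data")
    probs <- matrix(0, model$cfg$n_classes, N)
    for (start in seq(1, N, by = batch_size)) {
      idx <- start:min(start + batch_size - 1, N)
      probs[, idx] <- predict_model(model, data$x[, , , idx, drop = FALSE])
    }
    y_pred <- apply(probs, 2, which.max)
    rep <- classification_metrics(data$y, y_pred)
    aucs <- vapply(seq_len(nrow(probs)), function(k) {
      yk <- as.integer(data$y == k)
      if (sum(yk) == 0 || sum(yk) == N) return(NA_real_)
      roc_auc(yk, probs[k, ])$auc
    }, 0)
    rep$auc <- if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE)
    rep$n <- N
    rep
  } else {
    if (is.null(dim(data$y))) stopf("segmentation model evaluated on non-mask data")
    per <- matrix(0, N, 4, dimnames = list(NULL, c("dice", "iou", "precision", "recall")))
    for (start in seq(1, N, by = batch_size)) {
      idx <- start:min(start + batch_size - 1, N)
      pr <- predict_model(model, data$x[, , , idx, drop = FALSE])
      for (j in seq_along(idx)) {
        m <- segmentation_metrics((pr[, , 1, j] >= 0.5) * 1, data$y[, , 1, idx[j]])
        per[idx[j], ] <- c(m$dice, m$iou,
                           ifelse(is.na(m$precision), 0, m$precision),
                           ifelse(is.na(m$recall), 0, m$recall))
      }
    }
    out <- as.list(colMeans(per))
    out$per_image <- per
    out$n <- N
    class(out) <- "modse2_metrics"
    out
  }
}

# --- checkpoints ------------------------------------------------------------

flatten_params <- function(model) {
  out <- list()
  for (nm in names(model$layers)) {
    for (pn in names(model$layers[[nm]]$params)) {
      out[[paste(nm, pn, sep = ".")]] <- model$layers[[nm]]$params[[pn]]
    }
    st <- model$layers[[nm]]$state
    if (!is.null(st)) {
      for (sn in names(st)) out[[paste(nm, "state", sn, sep = ".")]] <- st[[sn]]
    }
  }
  out
}

#' Save a model checkpoint
#'
#' Writes a directory holding `config.yaml` (architecture configuration) and
#' `params.rds` (flat named-parameter archive, including batch-norm running
#' statistics).
#'
#' @param model a `modse2_model`.
#' @param dir checkpoint directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$cfg
  meta <- list(kind = if (isTRUE(model$baseline)) "baseline" else model$task,
               config = cfg[setdiff(names(cfg), "seed")])
  if (isTRUE(model$baseline)) {
    meta$baseline_widths <- list(
      stem = model$layers$stem$Cout,
      blocks = vapply(grep("^block\\d+_conv$", names(model$layers), value = TRUE),
                      function(nm) model$layers[[nm]]$Cout, 0L),
      fc = model$layers$fc1$Cout)
  }
  yaml::write_yaml(meta, file.path(dir, "config.yaml"))
  saveRDS(flatten_params(model), file.path(dir, "params.rds"))
  invisible(dir)
}

#' Load a model checkpoint
#'
#' Rebuilds the architecture from `config.yaml` and restores parameters;
#' a checkpoint whose parameter shapes disagree with the rebuilt
#' architecture raises an error naming the first mismatched field.
#'
#' @param dir checkpoint directory written by [save_model()].
#' @return a `modse2_model`.
#' @export
load_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cf <- meta$config
  cfg <- model_config(task = cf$task, n_orientations = cf$n_orientations,
                      extent = cf$extent, in_channels = cf$in_channels,
                      stem_filters = cf$stem_filters,
                      lifting_filters = cf$lifting_filters,
                      block_channels = unlist(cf$block_channels),
                      pool_lift = cf$pool_lift, se_ratio = cf$se_ratio,
                      dropout = cf$dropout, fc_width = cf$fc_width,
                      n_classes = cf$n_classes, mask_channels = cf$mask_channels,
                      kernel = cf$kernel, seed = 1L)
  model <- switch(meta$kind,
                  cls = build_classifier(cfg),
                  seg = build_segmenter(cfg),
                  baseline = {
                    ref <- build_classifier(cfg)
                    build_baseline_cnn(cfg, ref)
                  },
                  stopf("unknown checkpoint kind '%s'", meta$kind))
  flat <- readRDS(file.path(dir, "params.rds"))
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    nm <- parts[1]
    if (is.null(model$layers[[nm]])) stopf("checkpoint field '%s' has no matching layer", key)
    if (length(parts) == 3 && parts[2] == "state") {
      model$layers[[nm]]$state[[parts[3]]] <- flat[[key]]
    } else {
      cur <- model$layers[[nm]]$params[[parts[2]]]
      if (is.null(cur)) stopf("checkpoint field '%s' has no matching parameter", key)
      if (!identical(dim(cur) %||% length(cur), dim(flat[[key]]) %||% length(flat[[key]]))) {
        stopf("checkpoint field '%s' has mismatched shape", key)
      }
      model$layers[[nm]]$params[[parts[2]]] <- flat[[key]]
    }
  }
  model
}
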