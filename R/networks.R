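# Reference architectures.  A model is a named list of layers plus a linear
# "program" (layer / save / concat steps) that the generic runner executes;
# saves and concats express the U-Net-style skip connections of the
# segmentation decoder, and backward passes walk the program in reverse.

#' Model configuration
#'
#' Collects the architectural knobs shared by the classification and
#' segmentation networks.  The defaults mirror the reference design (3x3
#' stem with 32 filters, 64 lifting filters, two group-convolution blocks);
#' the `small` presets used throughout the examples shrink widths and extent
#' so everything runs on a desk CPU.
#'
#' @param task `"cls"` or `"seg"`.
#' @param n_orientations number of discrete orientations `O`.
#' @param extent input image side length (square inputs).
#' @param in_channels input channels (1 for grayscale).
#' @param stem_filters width of the stem convolution (weights tied over C4
#'   rotation orbits so the stem commutes with 90-degree rotations).
#' @param lifting_filters number of base filters in the lifting layer.
#' @param block_channels integer vector of group-convolution block widths.
#' @param pool_lift average-pooling factor applied right after lifting.
#' @param se_ratio squeeze-and-excitation reduction ratio.
#' @param dropout dropout probability in the classification head.
#' @param fc_width hidden width of the classification head.
#' @param n_classes number of classes (classification).
#' @param mask_channels output channels of the segmentation head.
#' @param kernel spatial kernel size (odd).
#' @param decoder_kernel spatial kernel size of the segmentation decoder's
#'   transposed group convolutions (defaults to `kernel`; the desk-scale
#'   presets use 1, leaving the spatial detail to the skip connections).
#' @param seed optional seed fixing parameter initialization.
#' @return a `modse2_config` list.
#' @export
model_config <- function(task = c("cls", "seg"), n_orientations = 8L,
                         extent = 256L, in_channels = 1L,
                         stem_filters = 32L, lifting_filters = 64L,
                         block_channels = c(64L, 128L), pool_lift = 2L,
                         se_ratio = 16L, dropout = 0.4, fc_width = 256L,
                         n_classes = 5L, mask_channels = 1L, kernel = 3L,
                         decoder_kernel = NULL, seed = NULL) {
  task <- match.arg(task)
  cfg <- list(task = task, n_orientations = as.integer(n_orientations),
              extent = as.integer(extent), in_channels = as.integer(in_channels),
              stem_filters = as.integer(stem_filters),
              lifting_filters = as.integer(lifting_filters),
              block_channels = as.integer(block_channels),
              pool_lift = as.integer(pool_lift), se_ratio = as.integer(se_ratio),
              dropout = dropout, fc_width = as.integer(fc_width),
              n_classes = as.integer(n_classes),
              mask_channels = as.integer(mask_channels),
              kernel = as.integer(kernel),
              decoder_kernel = as.integer(decoder_kernel %||% kernel),
              seed = seed)
  if (any(c(cfg$stem_filters, cfg$lifting_filters, cfg$block_channels) < 1)) {
    stopf("all widths must be >= 1")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) stopf("dropout must be in [0, 1)")
  if (cfg$kernel %% 2 == 0) stopf("kernel size must be odd")
  total_pool <- cfg$pool_lift * 2L^(length(cfg$block_channels) - 1L)
  if (cfg$extent %% total_pool != 0) {
    stopf("input extent %d must be divisible by the total pooling factor %d",
          cfg$extent, total_pool)
  }
  class(cfg) <- "modse2_config"
  cfg
}

step_layer <- function(name) list(kind = "layer", layer = name)
step_save <- function(slot) list(kind = "save", slot = slot)
step_concat <- function(slot) list(kind = "concat", slot = slot)

# Channel axis is the second-to-last ([H,W,O,C,B] -> 4, [H,W,C,B] -> 3);
# both concatenation and splitting are contiguous block copies in C++.
concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  ax <- length(da) - 1L
  nspat <- as.integer(prod(da[seq_len(ax - 1L)]))
  out <- cpp_concat_chan(a, b, nspat, da[ax], db[ax], da[length(da)])
  dim(out) <- replace(da, ax, da[ax] + db[ax])
  out
}

split_channels <- function(x, n_first) {
  d <- dim(x)
  ax <- length(d) - 1L
  nspat <- as.integer(prod(d[seq_len(ax - 1L)]))
  sp <- cpp_split_chan(x, nspat, as.integer(n_first), d[ax] - as.integer(n_first),
                       d[length(d)])
  dim(sp$a) <- replace(d, ax, as.integer(n_first))
  dim(sp$b) <- replace(d, ax, d[ax] - as.integer(n_first))
  sp
}

# A group-convolution block: conv -> BN -> SE -> ReLU (conv biases are
# redundant under BN and omitted).
append_block <- function(layers, program, prefix, O, Cin, Cout, k, r,
                         kh = 3L) {
  layers[[paste0(prefix, "_gconv")]] <-
    init_layer("gconv", kh = kh, kw = kh, O = O, Cin = Cin, Cout = Cout,
               stride = 1L, padding = "same", bias = FALSE)
  layers[[paste0(prefix, "_bn")]] <- init_layer("bn", C = Cout, O = O)
  layers[[paste0(prefix, "_se")]] <- init_layer("se", C = Cout, O = O, r = r)
  layers[[paste0(prefix, "_relu")]] <- list(type = "relu", params = list())
  program <- c(program, lapply(paste0(prefix, c("_gconv", "_bn", "_se", "_relu")),
                               step_layer))
  list(layers = layers, program = program)
}

#' Build the Mod-Cls-SE(2) reference classifier
#'
#' Pipeline: C4-symmetric stem convolution, lifting onto `O` orientations,
#' average pooling, a stack of group-convolution blocks
#' (conv, batch norm, squeeze-and-excitation, ReLU, pool), orientation
#' projection, global average pooling, and a fully connected softmax head.
#' In eval mode the softmax output is invariant to 90-degree rotations of
#' the input (exactly, up to floating-point accumulation).
#'
#' @param cfg a [model_config()] with `task = "cls"`.
#' @return a `modse2_model` object.
#' @export
build_classifier <- function(cfg) {
  stopifnot(inherits(cfg, "modse2_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  O <- cfg$n_orientations
  layers <- list()
  program <- list()
  layers$stem <- init_layer("symconv", Cin = cfg$in_channels,
                            Cout = cfg$stem_filters, bias = TRUE)
  layers$stem_relu <- list(type = "relu", params = list())
  layers$lifting <- init_layer("lifting", kh = cfg$kernel, kw = cfg$kernel,
                               O = O, Cin = cfg$stem_filters,
                               Cout = cfg$lifting_filters, stride = 1L,
                               padding = "same", bias = TRUE)
  layers$pool_lift <- list(type = "pool", factor = cfg$pool_lift, params = list())
  program <- c(program, lapply(c("stem", "stem_relu", "lifting", "pool_lift"),
                               step_layer))
  Cin <- cfg$lifting_filters
  nb <- length(cfg$block_channels)
  for (i in seq_len(nb)) {
    bl <- append_block(layers, program, paste0("block", i), O, Cin,
                       cfg$block_channels[i], cfg$kernel, cfg$se_ratio)
    layers <- bl$layers; program <- bl$program
    if (i == nb) program <- c(program, list(step_save("last_block")))
    layers[[paste0("block", i, "_pool")]] <- list(type = "pool", factor = 2L,
                                                  params = list())
    program <- c(program, list(step_layer(paste0("block", i, "_pool"))))
    Cin <- cfg$block_channels[i]
  }
  layers$project <- list(type = "project", params = list())
  layers$gap <- list(type = "gap", params = list())
  layers$fc1 <- init_layer("fc", Cin = Cin, Cout = cfg$fc_width)
  layers$fc1_relu <- list(type = "relu", params = list())
  layers$head_dropout <- list(type = "dropout", p = cfg$dropout, params = list())
  layers$fc2 <- init_layer("fc", Cin = cfg$fc_width, Cout = cfg$n_classes)
  program <- c(program, lapply(c("project", "gap", "fc1", "fc1_relu",
                                 "head_dropout", "fc2"), step_layer))
  structure(list(task = "cls", cfg = cfg, layers = layers, program = program),
            class = "modse2_model")
}

#' Build the Mod-Seg-SE(2) reference segmenter
#'
#' U-Net-style encoder/decoder on the SE(2) group: the encoder repeats the
#' classifier trunk (stem, lifting, group-convolution blocks with pooling);
#' the decoder mirrors it with stride-2 group deconvolutions, concatenating
#' the encoder orientation feature maps at matching resolutions, followed by
#' a 1x1 merge group convolution per stage.  An orientation projection, 1x1
#' convolution and sigmoid produce the mask probability map at the input
#' resolution.
#'
#' @param cfg a [model_config()] with `task = "seg"`.
#' @return a `modse2_model` object.
#' @export
build_segmenter <- function(cfg) {
  stopifnot(inherits(cfg, "modse2_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  O <- cfg$n_orientations
  ch <- cfg$block_channels
  nb <- length(ch)
  if (nb < 2) stopf("segmenter needs at least two encoder blocks")
  layers <- list()
  program <- list()
  layers$stem <- init_layer("symconv", Cin = cfg$in_channels,
                            Cout = cfg$stem_filters, bias = TRUE)
  layers$stem_relu <- list(type = "relu", params = list())
  layers$lifting <- init_layer("lifting", kh = cfg$kernel, kw = cfg$kernel,
                               O = O, Cin = cfg$stem_filters,
                               Cout = cfg$lifting_filters, stride = 1L,
                               padding = "same", bias = TRUE)
  program <- c(program, lapply(c("stem", "stem_relu", "lifting"), step_layer),
               list(step_save("skip0")))
  layers$pool_lift <- list(type = "pool", factor = cfg$pool_lift, params = list())
  program <- c(program, list(step_layer("pool_lift")))
  Cin <- cfg$lifting_filters
  for (i in seq_len(nb)) {
    if (i > 1) {
      layers[[paste0("enc", i, "_pool")]] <- list(type = "pool", factor = 2L,
                                                  params = list())
      program <- c(program, list(step_layer(paste0("enc", i, "_pool"))))
    }
    bl <- append_block(layers, program, paste0("enc", i), O, Cin, ch[i],
                       cfg$kernel, cfg$se_ratio)
    layers <- bl$layers; program <- bl$program
    if (i < nb) program <- c(program, list(step_save(paste0("skip", i))))
    Cin <- ch[i]
  }
  # decoder: mirror the encoder back up to full resolution
  for (i in rev(seq_len(nb - 1))) {
    up_ch <- ch[i]
    layers[[paste0("dec", i, "_up")]] <-
      init_layer("gdeconv", kh = cfg$decoder_kernel, kw = cfg$decoder_kernel,
                 O = O, Cup = up_ch, Cdown = Cin, stride = 2L, bias = TRUE)
    layers[[paste0("dec", i, "_relu")]] <- list(type = "relu", params = list())
    program <- c(program, lapply(paste0("dec", i, c("_up", "_relu")), step_layer),
                 list(step_concat(paste0("skip", i))))
    bl <- append_block(layers, program, paste0("dec", i), O, up_ch + ch[i],
                       up_ch, cfg$kernel, cfg$se_ratio, kh = 1L)
    layers <- bl$layers; program <- bl$program
    Cin <- up_ch
  }
  layers$dec0_up <- init_layer("gdeconv", kh = cfg$decoder_kernel,
                               kw = cfg$decoder_kernel, O = O,
                               Cup = cfg$lifting_filters, Cdown = Cin,
                               stride = cfg$pool_lift, bias = TRUE)
  layers$dec0_relu <- list(type = "relu", params = list())
  program <- c(program, lapply(c("dec0_up", "dec0_relu"), step_layer),
               list(step_concat("skip0")))
  bl <- append_block(layers, program, "dec0", O, 2L * cfg$lifting_filters,
                     cfg$lifting_filters, cfg$kernel, cfg$se_ratio, kh = 1L)
  layers <- bl$layers; program <- bl$program
  program <- c(program, list(step_save("last_block")))
  layers$project <- list(type = "project", params = list())
  layers$head <- init_layer("conv", kh = 1L, kw = 1L,
                            Cin = cfg$lifting_filters,
                            Cout = cfg$mask_channels, stride = 1L,
                            padding = "same", bias = TRUE)
  layers$head_sigmoid <- list(type = "sigmoid", params = list())
  program <- c(program, lapply(c("project", "head", "head_sigmoid"), step_layer))
  structure(list(task = "seg", cfg = cfg, layers = layers, program = program),
            class = "modse2_model")
}

# --- generic program runner -------------------------------------------------

run_program <- function(model, x, training = FALSE) {
  saved <- list()
  caches <- vector("list", length(model$program))
  states <- list()
  concat_split <- list()
  for (i in seq_along(model$program)) {
    st <- model$program[[i]]
    if (st$kind == "layer") {
      lf <- layer_forward(model$layers[[st$layer]], x, training)
      caches[[i]] <- lf$cache
      if (!is.null(lf$state)) states[[st$layer]] <- lf$state
      x <- lf$out
    } else if (st$kind == "save") {
      saved[[st$slot]] <- x
    } else if (st$kind == "concat") {
      d <- dim(x)
      concat_split[[as.character(i)]] <- d[length(d) - 1L]
      x <- concat_channels(x, saved[[st$slot]])
    }
  }
  list(out = x, caches = caches, saved = saved, states = states,
       concat_split = concat_split)
}

run_backward <- function(model, fwd, dout) {
  grads <- list()
  slot_grad <- list()
  for (i in rev(seq_along(model$program))) {
    st <- model$program[[i]]
    if (st$kind == "layer") {
      lb <- layer_backward(model$layers[[st$layer]], fwd$caches[[i]], dout)
      if (length(lb$grads)) {
        if (is.null(grads[[st$layer]])) {
          grads[[st$layer]] <- lb$grads
        } else {
          grads[[st$layer]] <- Map(`+`, grads[[st$layer]], lb$grads)
        }
      }
      dout <- lb$dx
    } else if (st$kind == "save") {
      sg <- slot_grad[[st$slot]]
      if (!is.null(sg)) dout <- dout + sg
    } else if (st$kind == "concat") {
      n1 <- fwd$concat_split[[as.character(i)]]
      sp <- split_channels(dout, n1)
      prev <- slot_grad[[st$slot]]
      slot_grad[[st$slot]] <- if (is.null(prev)) sp$b else prev + sp$b
      dout <- sp$a
    }
  }
  list(grads = grads, dx = dout)
}

# Forward pass returning task-level outputs: softmax probabilities [K, B]
# for classification, mask probability maps [H, W, C, B] for segmentation.
#' Run a model forward
#'
#' @param model a `modse2_model`.
#' @param x input batch `[H, W, C, B]` (a single `[H, W, C]` image or
#'   `[H, W]` matrix is promoted to a batch of one).
#' @param training logical; enables dropout and batch statistics.
#' @return classification: a `[n_classes, B]` matrix of softmax
#'   probabilities; segmentation: a `[H, W, mask_channels, B]` array of
#'   sigmoid probabilities.
#' @export
predict_model <- function(model, x, training = FALSE) {
  x <- as_input_batch(x)
  fwd <- run_program(model, x, training)
  if (model$task == "cls") softmax_cols(fwd$out) else fwd$out
}

as_input_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stopf("input must be an array")
  if (length(d) == 2) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 3) x <- array(x, c(d, 1L))
  x
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), `-`)
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

#' @export
print.modse2_model <- function(x, ...) {
  cat(sprintf("Mod-%s-SE(2) model: O=%d, extent=%d, %d layers, %s parameters\n",
              if (x$task == "cls") "Cls" else "Seg",
              x$cfg$n_orientations, x$cfg$extent, length(x$layers),
              format(model_parameter_count(x), big.mark = ",")))
  invisible(x)
}

# --- parameter accounting ---------------------------------------------------

#' Layer parameter specification
#'
#' @param kh,kw kernel extent.
#' @param Cin,Cout input/output channels.
#' @param G channel-group count (grouped convolution, not the SE(2) group).
#' @param bias whether the layer has a bias vector.
#' @export
layer_param_spec <- function(kh, kw, Cin, Cout, G = 1L, bias = TRUE) {
  if (G > 1 && (Cin %% G != 0 || Cout %% G != 0)) {
    stopf("Cin and Cout must be divisible by G")
  }
  list(kh = kh, kw = kw, Cin = Cin, Cout = Cout, G = as.integer(G),
       bias = isTRUE(bias))
}

#' Count the trainable parameters of a convolutional layer
#'
#' For `G = 1` this is the standard `kh*kw*Cin*Cout + Cout` count.  For
#' channel-grouped layers two conventions are provided: `"as-printed"`
#' computes `(kh*kw*Cin/G)*(Cout/G) + Cout`, dividing the output channels by
#' the group count as well; `"standard-grouped"` computes the conventional
#' `(kh*kw*Cin/G)*Cout + Cout`.
#'
#' @param spec a [layer_param_spec()].
#' @param mode `"as-printed"` (default) or `"standard-grouped"`.
#' @return integer parameter count.
#' @export
count_layer_parameters <- function(spec, mode = c("as-printed", "standard-grouped")) {
  mode <- match.arg(mode)
  b <- if (spec$bias) spec$Cout else 0L
  if (spec$G == 1L) return(spec$kh * spec$kw * spec$Cin * spec$Cout + b)
  if (spec$Cin %% spec$G != 0 || spec$Cout %% spec$G != 0) {
    stopf("Cin and Cout must be divisible by G")
  }
  if (mode == "as-printed") {
    (spec$kh * spec$kw * spec$Cin / spec$G) * (spec$Cout / spec$G) + b
  } else {
    (spec$kh * spec$kw * spec$Cin / spec$G) * spec$Cout + b
  }
}

#' Total trainable parameter count of a model
#'
#' Sums the lengths of every parameter array (SE(2) group kernels contribute
#' `kh*kw*O*Cin*Cout` each, plus biases).
#'
#' @param model a `modse2_model`.
#' @export
model_parameter_count <- function(model) {
  sum(vapply(model$layers,
             function(ly) sum(vapply(ly$params, length, 0L)), 0))
}

# --- parameter-matched plain CNN baseline ----------------------------------

baseline_widths <- function(cfg, scale) {
  list(stem = max(1L, round(cfg$stem_filters * scale)),
       blocks = pmax(1L, round(cfg$block_channels * scale)),
       fc = cfg$fc_width)
}

baseline_count <- function(cfg, w) {
  k <- cfg$kernel
  n <- k * k * cfg$in_channels * w$stem + w$stem
  Cin <- w$stem
  for (C in w$blocks) {
    n <- n + k * k * Cin * C          # conv (no bias, BN follows)
    n <- n + 2 * C                    # BN affine
    Cin <- C
  }
  n <- n + Cin * w$fc + w$fc + w$fc * cfg$n_classes + cfg$n_classes
  n
}

#' Build a parameter-matched plain CNN baseline
#'
#' A conventional convolution/pool/FC network with the same depth pattern and
#' spatial schedule as the matched Mod-Cls-SE(2) model but no lifting or
#' group structure; widths are scaled so the trainable parameter count lands
#' within 10% of the matched model.
#'
#' @param cfg the [model_config()] used for the matched model.
#' @param match the `modse2_model` whose parameter count to match.
#' @return a `modse2_model` with `task = "cls"`.
#' @export
build_baseline_cnn <- function(cfg, match) {
  target <- model_parameter_count(match)
  scales <- seq(0.05, 20, by = 0.01)
  counts <- vapply(scales, function(s) baseline_count(cfg, baseline_widths(cfg, s)), 0)
  best <- which.min(abs(counts - target))
  if (abs(counts[best] - target) / target > 0.10) {
    stopf("cannot match parameter count within 10%%: achievable range [%d, %d], target %d",
          min(counts), max(counts), target)
  }
  w <- baseline_widths(cfg, scales[best])
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1L)
  k <- cfg$kernel
  layers <- list()
  program <- list()
  layers$stem <- init_layer("conv", kh = k, kw = k, Cin = cfg$in_channels,
                            Cout = w$stem, stride = 1L, padding = "same",
                            bias = TRUE)
  layers$stem_relu <- list(type = "relu", params = list())
  layers$pool0 <- list(type = "pool", factor = cfg$pool_lift, params = list())
  program <- c(program, lapply(c("stem", "stem_relu", "pool0"), step_layer))
  Cin <- w$stem
  for (i in seq_along(w$blocks)) {
    nm <- paste0("block", i)
    layers[[paste0(nm, "_conv")]] <- init_layer("conv", kh = k, kw = k,
                                                Cin = Cin, Cout = w$blocks[i],
                                                stride = 1L, padding = "same",
                                                bias = FALSE)
    layers[[paste0(nm, "_bn")]] <- init_layer("bn", C = w$blocks[i])
    layers[[paste0(nm, "_relu")]] <- list(type = "relu", params = list())
    layers[[paste0(nm, "_pool")]] <- list(type = "pool", factor = 2L, params = list())
    program <- c(program, lapply(paste0(nm, c("_conv", "_bn", "_relu", "_pool")),
                                 step_layer))
    Cin <- w$blocks[i]
  }
  layers$gap <- list(type = "gap", params = list())
  layers$fc1 <- init_layer("fc", Cin = Cin, Cout = w$fc)
  layers$fc1_relu <- list(type = "relu", params = list())
  layers$head_dropout <- list(type = "dropout", p = cfg$dropout, params = list())
  layers$fc2 <- init_layer("fc", Cin = w$fc, Cout = cfg$n_classes)
  program <- c(program, lapply(c("gap", "fc1", "fc1_relu", "head_dropout", "fc2"),
                               step_layer))
  structure(list(task = "cls", cfg = cfg, layers = layers, program = program,
                 baseline = TRUE),
            class = "modse2_model")
}

# --- activation heatmap -----------------------------------------------------

#' Activation heatmap of the final group-convolution block
#'
#' Averages the last group-convolution block's activations over channels and
#' orientations, rectifies, min-max scales to [0, 1], and upsamples to the
#' input extent.
#'
#' @param model a `modse2_model` (eval mode is used).
#' @param img a `[H, W]` or `[H, W, C]` image.
#' @return a `[H, W]` matrix in [0, 1].
#' @export
activation_heatmap <- function(model, img) {
  x <- as_input_batch(img)
  fwd <- run_program(model, x, training = FALSE)
  src <- fwd$saved$last_block
  if (is.null(src)) stopf("model records no block activations")
  d <- dim(src)
  hm <- apply(array(src, c(d[1], d[2], prod(d[-(1:2)]))), c(1, 2), mean)
  hm <- minmax01(pmax(hm, 0))
  resize_bilinear(hm, dim(x)[1], dim(x)[2])
}
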