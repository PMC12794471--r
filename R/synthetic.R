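# Seeded synthetic image generators.  Every experiment in the package runs
# on these: oriented geometric shapes over noisy backgrounds (classification),
# smooth random blobs with exact masks (segmentation), and small axis-aligned
# bright squares (fine-scale detection).  Images are built as
# base + offset * support + Gaussian noise, clipped to [0, 1], so the mask is
# exactly the set of pixels that received the foreground offset.

#' Synthetic dataset specification
#'
#' @param task `"cls"`, `"seg"` or `"finescale"`.
#' @param n_samples number of images.
#' @param extent square image side (>= 16).
#' @param shapes class names for the classification task.
#' @param rotate if `FALSE` ("upright" mode) shapes are not rotated;
#'   otherwise pose angles are uniform over the full circle.
#' @param jitter maximum center translation in pixels (each axis).
#' @param sigma background Gaussian noise standard deviation.
#' @param offset foreground minus background intensity.
#' @param background base background intensity.
#' @param sides square side lengths for the fine-scale task.
#' @param seed RNG seed (full determinism).
#' @export
synthetic_spec <- function(task = c("cls", "seg", "finescale"),
                           n_samples = 100L, extent = 64L,
                           shapes = c("disk", "square", "triangle", "annulus", "cross"),
                           rotate = TRUE, jitter = NULL, sigma = 0.1,
                           offset = 0.5, background = 0.2,
                           sides = c(3L, 5L, 7L, 9L), seed = 1L) {
  task <- match.arg(task)
  extent <- as.integer(extent)
  if (extent < 16) stopf("extent must be >= 16")
  if (n_samples < 1) stopf("n_samples must be >= 1")
  if (sigma < 0) stopf("sigma must be >= 0")
  if (task == "finescale" && any(sides >= extent / 2)) {
    stopf("side lengths must be < extent/2")
  }
  list(task = task, n_samples = as.integer(n_samples), extent = extent,
       shapes = shapes, rotate = isTRUE(rotate),
       jitter = jitter %||% round(extent / 8), sigma = sigma, offset = offset,
       background = background, sides = as.integer(sides),
       seed = as.integer(seed))
}

# Membership test of a shape at the origin in its own (unrotated) frame.
# u, v are centered coordinates; size is the characteristic radius.
shape_support <- function(shape, u, v, size) {
  switch(shape,
    disk = u^2 + v^2 <= size^2,
    square = pmax(abs(u), abs(v)) <= size * 0.85,
    triangle = {
      # equilateral triangle, vertex up, circumradius = size (intersection of
      # three half-planes at inradius size/2)
      keep <- rep(TRUE, length(u))
      for (thv in pi / 2 + c(0, 2, 4) * pi / 3) {
        keep <- keep & (u * cos(thv) + v * sin(thv) >= -size / 2)
      }
      keep
    },
    annulus = {
      r2 <- u^2 + v^2
      r2 <= size^2 & r2 >= (0.55 * size)^2
    },
    cross = {
      w <- size * 0.35
      (abs(u) <= w & abs(v) <= size) | (abs(v) <= w & abs(u) <= size)
    },
    stopf("unknown shape '%s'", shape))
}

# Render one shape at pose (angle radians CCW, center offset (du, dv)) onto
# an extent x extent grid; returns the logical support.
render_shape <- function(shape, extent, size, angle, du, dv) {
  c0 <- (extent - 1) / 2
  grid <- expand.grid(row = seq_len(extent) - 1, col = seq_len(extent) - 1)
  u <- grid$col - c0 - du
  v <- c0 - grid$row - dv
  Rinv <- rotation_matrix(-angle)
  uu <- Rinv[1, 1] * u + Rinv[1, 2] * v
  vv <- Rinv[2, 1] * u + Rinv[2, 2] * v
  matrix(shape_support(shape, uu, vv, size), extent, extent)
}

compose_image <- function(support, spec) {
  img <- spec$background + spec$offset * support
  if (spec$sigma > 0) img <- img + rnorm(length(img), sd = spec$sigma)
  clip01(matrix(img, nrow(support), ncol(support)))
}

#' Generate a synthetic shape-classification dataset
#'
#' Each image contains one shape of a (balanced) class, rotated by a uniform
#' angle unless `spec$rotate` is `FALSE` ("upright" mode), translated within
#' the jitter range, over a Gaussian-noise background.
#'
#' @param spec a [synthetic_spec()] with `task = "cls"`.
#' @return a dataset list `(task, x, y, classes, meta)`; `meta` records the
#'   pose of every sample.
#' @export
gen_classification_set <- function(spec) {
  if (spec$task != "cls") stopf("spec task must be 'cls'")
  set.seed(spec$seed)
  n <- spec$n_samples; K <- length(spec$shapes)
  labels <- rep(seq_len(K), length.out = n)[sample.int(n)]
  x <- array(0, c(spec$extent, spec$extent, 1L, n))
  meta <- data.frame(index = seq_len(n), class = spec$shapes[labels],
                     angle = 0, du = 0, dv = 0, size = 0)
  for (i in seq_len(n)) {
    size <- runif(1, 0.14, 0.26) * spec$extent
    angle <- if (spec$rotate) runif(1, 0, 2 * pi) else 0
    du <- runif(1, -spec$jitter, spec$jitter)
    dv <- runif(1, -spec$jitter, spec$jitter)
    sup <- render_shape(spec$shapes[labels[i]], spec$extent, size, angle, du, dv)
    x[, , 1, i] <- compose_image(sup, spec)
    meta$angle[i] <- angle; meta$du[i] <- du; meta$dv[i] <- dv; meta$size[i] <- size
  }
  list(task = "cls", x = x, y = labels, classes = spec$shapes, meta = meta,
       spec = spec)
}

#' Generate a synthetic blob-segmentation dataset
#'
#' Each image contains 1-3 smooth random blobs (unions of randomly oriented,
#' boundary-perturbed ellipses) brighter than the background; the mask is
#' exactly the rendered foreground support.
#'
#' @param spec a [synthetic_spec()] with `task = "seg"`.
#' @return a dataset list `(task, x, y, meta)`.
#' @export
gen_segmentation_set <- function(spec) {
  if (spec$task != "seg") stopf("spec task must be 'seg'")
  set.seed(spec$seed)
  n <- spec$n_samples; E <- spec$extent
  x <- array(0, c(E, E, 1L, n))
  y <- array(0, c(E, E, 1L, n))
  c0 <- (E - 1) / 2
  grid <- expand.grid(row = seq_len(E) - 1, col = seq_len(E) - 1)
  nblobs <- integer(n)
  for (i in seq_len(n)) {
    nb <- sample.int(3, 1)
    nblobs[i] <- nb
    sup <- matrix(FALSE, E, E)
    for (b in seq_len(nb)) {
      cu <- runif(1, -E / 4, E / 4); cv <- runif(1, -E / 4, E / 4)
      a <- runif(1, 0.08, 0.2) * E
      bb <- a * runif(1, 0.5, 1)
      th <- runif(1, 0, pi)
      ph0 <- runif(1, 0, 2 * pi)
      amp <- runif(1, 0.05, 0.18)
      u <- grid$col - c0 - cu
      v <- c0 - grid$row - cv
      Rinv <- rotation_matrix(-th)
      uu <- Rinv[1, 1] * u + Rinv[1, 2] * v
      vv <- Rinv[2, 1] * u + Rinv[2, 2] * v
      r2 <- (uu / a)^2 + (vv / bb)^2
      phi <- atan2(vv, uu)
      sup <- sup | matrix(r2 <= (1 + amp * sin(3 * phi + ph0))^2, E, E)
    }
    x[, , 1, i] <- compose_image(sup, spec)
    y[, , 1, i] <- sup * 1
  }
  list(task = "seg", x = x, y = y,
       meta = data.frame(index = seq_len(n), n_blobs = nblobs), spec = spec)
}

#' Generate the fine-scale square-detection dataset
#'
#' Each image contains exactly one axis-aligned bright square with side
#' length drawn uniformly from `spec$sides`, at a uniform random interior
#' position on whole-pixel coordinates, so the mask marks exactly `s^2`
#' pixels; per-image metadata records the side length.
#'
#' @param spec a [synthetic_spec()] with `task = "finescale"`.
#' @return a dataset list `(task, x, y, meta)`; `meta$side` holds the side
#'   length per image.
#' @export
gen_finescale_set <- function(spec) {
  if (spec$task != "finescale") stopf("spec task must be 'finescale'")
  set.seed(spec$seed)
  n <- spec$n_samples; E <- spec$extent
  x <- array(0, c(E, E, 1L, n))
  y <- array(0, c(E, E, 1L, n))
  sides <- spec$sides[1 + (sample.int(length(spec$sides) * 1000, n) - 1) %% length(spec$sides)]
  margin <- 2L
  for (i in seq_len(n)) {
    s <- sides[i]
    r0 <- sample(seq(margin + 1L, E - s - margin), 1)
    c0 <- sample(seq(margin + 1L, E - s - margin), 1)
    sup <- matrix(FALSE, E, E)
    sup[r0:(r0 + s - 1L), c0:(c0 + s - 1L)] <- TRUE
    x[, , 1, i] <- compose_image(sup, spec)
    y[, , 1, i] <- sup * 1
  }
  list(task = "finescale", x = x, y = y,
       meta = data.frame(index = seq_len(n), side = sides), spec = spec)
}

#' Write a generated dataset to disk
#'
#' PNG images (plus PNG masks for segmentation tasks), a `manifest.csv`
#' consumable by [load_manifest()], and a JSON sidecar recording the
#' generator specification and per-sample metadata.
#'
#' @param ds a dataset from one of the generators.
#' @param dir output directory.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(ds$x)[4]
  img_names <- sprintf("img_%04d.png", seq_len(n))
  for (i in seq_len(n)) write_image_png(ds$x[, , , i], file.path(dir, img_names[i]))
  if (ds$task == "cls") {
    rows <- data.frame(image = img_names, label = ds$classes[ds$y])
  } else {
    mask_names <- sprintf("mask_%04d.png", seq_len(n))
    for (i in seq_len(n)) write_image_png(ds$y[, , , i], file.path(dir, mask_names[i]))
    rows <- data.frame(image = img_names, mask = mask_names)
  }
  write_manifest(rows, file.path(dir, "manifest.csv"))
  jsonlite::write_json(list(spec = ds$spec, meta = ds$meta),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
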