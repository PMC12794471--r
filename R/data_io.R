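# Image reading/writing, the preprocessing pipeline (resize, histogram
# equalization, [0,1] normalization) and paired image/mask augmentation.
# Supported formats: PNG (8/16-bit grayscale) and NIfTI-1 (.nii/.nii.gz,
# with an axial slice index).

#' Read a 2-D image
#'
#' PNG images are mapped linearly from their bit depth to [0, 1]; NIfTI
#' volumes yield the requested slice along the last stored axis (no
#' re-orientation is applied), min-max scaled to [0, 1].
#'
#' @param path file path (.png, .nii or .nii.gz).
#' @param nifti_slice slice index for NIfTI volumes.
#' @return a `[H, W, 1]` array with values in [0, 1].
#' @export
read_image <- function(path, nifti_slice = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]  # grayscale content expected
    array(img, c(dim(img), 1L))
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) == 2) {
      sl <- as.matrix(vol)
    } else {
      if (is.null(nifti_slice)) stopf("a slice index is required for NIfTI volumes")
      if (nifti_slice < 1 || nifti_slice > d[3]) {
        stopf("slice index %d out of range [1, %d]", nifti_slice, d[3])
      }
      sl <- vol[, , nifti_slice]
    }
    rng <- range(sl)
    if (rng[2] > rng[1]) sl <- (sl - rng[1]) / (rng[2] - rng[1]) else sl <- sl * 0
    array(sl, c(dim(sl), 1L))
  } else if (grepl("\\.(jpg|jpeg)$", lower)) {
    stopf("JPEG input is not supported; convert to PNG")
  } else {
    stopf("unrecognized image format: %s", path)
  }
}

#' Write a grayscale image as PNG
#'
#' Values are clipped to [0, 1] and stored at 8 bits per pixel (the maximum
#' round-trip quantization error is therefore 1/510).  For lossless storage
#' of real-valued images use NIfTI ([RNifti::writeNifti()]); [read_image()]
#' reads 16-bit PNGs produced elsewhere at full precision.
#'
#' @param img `[H, W]` matrix or `[H, W, 1]` array with values in [0, 1].
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  if (length(dim(img)) == 3) img <- img[, , 1]
  png::writePNG(clip01(img), path)
  invisible(path)
}

#' Preprocessing configuration
#'
#' @param target output extent (images become target x target).
#' @param equalize apply global histogram equalization.
#' @param normalize rescale to the [0, 1] range after equalization.
#' @param augment enable random rotation/scaling in [augment()].
#' @param rotation_limit maximum absolute augmentation rotation, degrees.
#' @param scale_limit maximum relative scale change (0.1 = +/-10%).
#' @param seed RNG seed for augmentation draws.
#' @export
preprocess_config <- function(target = 256L, equalize = TRUE, normalize = TRUE,
                              augment = FALSE, rotation_limit = 15,
                              scale_limit = 0.1, seed = NULL) {
  if (rotation_limit < 0) stopf("rotation limit must be >= 0")
  if (scale_limit < 0 || scale_limit >= 0.5) stopf("scale limit must be in [0, 0.5)")
  list(target = as.integer(target), equalize = isTRUE(equalize),
       normalize = isTRUE(normalize), augment = isTRUE(augment),
       rotation_limit = rotation_limit, scale_limit = scale_limit, seed = seed)
}

#' Global histogram equalization
#'
#' Cumulative-distribution mapping on the [0, 1] intensity range with
#' `nbins` bins; a constant image is returned unchanged (degenerate
#' histogram convention).
#'
#' @param img `[H, W]` matrix or `[H, W, 1]` array with values in [0, 1].
#' @param nbins number of histogram bins.
#' @export
hist_equalize <- function(img, nbins = 256L) {
  d <- dim(img)
  v <- as.vector(img)
  if (max(v) - min(v) < .Machine$double.eps) return(img)
  bins <- pmin(pmax(ceiling(v * nbins), 1L), nbins)
  counts <- tabulate(bins, nbins)
  cdf <- cumsum(counts) / length(v)
  array(cdf[bins], d)
}

#' Preprocess an image
#'
#' Bilinear resize to `target x target`, optional global histogram
#' equalization, and [0, 1] normalization.
#'
#' @param img `[H, W]`, `[H, W, 1]` image.
#' @param cfg a [preprocess_config()].
#' @return a `[target, target, 1]` array in [0, 1].
#' @export
preprocess <- function(img, cfg = preprocess_config()) {
  d <- dim(img)
  if (is.null(d) || d[1] < 1 || d[2] < 1) stopf("zero-sized image")
  if (length(d) == 2) img <- array(img, c(d, 1L))
  out <- img
  if (dim(out)[1] != cfg$target || dim(out)[2] != cfg$target) {
    out <- array(resize_bilinear(out, cfg$target, cfg$target),
                 c(cfg$target, cfg$target, dim(img)[3]))
  }
  if (cfg$equalize) out <- hist_equalize(out)
  if (cfg$normalize) {
    rng <- range(out)
    if (rng[2] > rng[1]) out <- (out - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Jointly augment an image and (optionally) its mask
#'
#' Draws one rotation angle uniform in `[-rotation_limit, +rotation_limit]`
#' degrees and one scale factor uniform in `[1-scale_limit, 1+scale_limit]`,
#' and applies both about the image center: bilinear interpolation for the
#' image, nearest-neighbour with re-binarization for the mask.  With
#' augmentation disabled the inputs are returned unchanged.
#'
#' @param img `[H, W]` or `[H, W, 1]` image.
#' @param mask optional binary mask of matching extent.
#' @param cfg a [preprocess_config()]; draws use the current RNG state
#'   (seed it, or set `cfg$seed`).
#' @return `list(img, mask, angle, scale)`.
#' @export
augment <- function(img, mask = NULL, cfg = preprocess_config(augment = TRUE)) {
  d <- dim(img)
  if (length(d) == 2) img <- array(img, c(d, 1L))
  if (!is.null(mask) && !all(dim(mask)[1:2] == dim(img)[1:2])) {
    stopf("mask shape does not match image")
  }
  if (!cfg$augment) return(list(img = img, mask = mask, angle = 0, scale = 1))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  angle <- runif(1, -cfg$rotation_limit, cfg$rotation_limit)
  scale <- runif(1, 1 - cfg$scale_limit, 1 + cfg$scale_limit)
  out_img <- affine_about_center(img, angle, scale, "bilinear")
  out_mask <- NULL
  if (!is.null(mask)) {
    out_mask <- (affine_about_center(array(mask, c(dim(mask)[1:2], 1L)),
                                     angle, scale, "nearest")[, , 1] >= 0.5) * 1
  }
  list(img = out_img, mask = out_mask, angle = angle, scale = scale)
}

# Rotate by `angle` degrees CCW then scale, both about the image center;
# output(p) = I(R_{-theta} p / s) with zero fill.
affine_about_center <- function(img, angle, scale, interpolation) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  grid <- expand.grid(row = seq_len(H) - 1, col = seq_len(W) - 1)
  u <- grid$col - cx; v <- cy - grid$row
  th <- angle * pi / 180
  Rinv <- rotation_matrix(-th)
  qu <- (Rinv[1, 1] * u + Rinv[1, 2] * v) / scale
  qv <- (Rinv[2, 1] * u + Rinv[2, 2] * v) / scale
  rows <- cy - qv + 1; cols <- cx + qu + 1
  sampler <- if (interpolation == "nearest") nearest_sample else bilinear_sample
  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    out[, , ch] <- matrix(sampler(img[, , ch], rows, cols), H, W)
  }
  out
}

# --- dataset manifests ------------------------------------------------------

#' Load a dataset manifest
#'
#' CSV with a header row: columns `image,label` (classification) or
#' `image,mask` (segmentation).  Paths are resolved relative to the
#' manifest's directory; referenced files must exist, and duplicate image
#' paths are an error.
#'
#' @param path manifest CSV path.
#' @param check_files verify that referenced files exist.
#' @return a `modse2_manifest` list with fields `rows` (data.frame),
#'   `kind` (`"cls"`/`"seg"`), `classes` (classification only).
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  rows <- read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  if (all(c("image", "label") %in% names(rows))) kind <- "cls"
  else if (all(c("image", "mask") %in% names(rows))) kind <- "seg"
  else stopf("manifest must have columns image,label or image,mask")
  if (anyDuplicated(rows$image)) {
    stopf("duplicate image paths in manifest (first: row %d)",
          which(duplicated(rows$image))[1])
  }
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  if (check_files) {
    for (i in seq_len(nrow(rows))) {
      f <- resolve(rows$image[i])
      if (!file.exists(f)) stopf("manifest row %d: missing file %s", i, rows$image[i])
      if (kind == "seg") {
        fm <- resolve(rows$mask[i])
        if (!file.exists(fm)) stopf("manifest row %d: missing mask %s", i, rows$mask[i])
      }
    }
  }
  out <- list(rows = rows, kind = kind, base = base)
  if (kind == "cls") out$classes <- sort(unique(rows$label))
  class(out) <- "modse2_manifest"
  out
}

#' Write a dataset manifest
#'
#' @param manifest a `modse2_manifest` (or data.frame with the manifest
#'   columns).
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  rows <- if (inherits(manifest, "modse2_manifest")) manifest$rows else manifest
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Materialize a manifest as an in-memory dataset
#'
#' Reads every referenced image (and mask), optionally through
#' [preprocess()], and stacks them into the `[H, W, 1, N]` batch layout the
#' trainer consumes.  Classification labels are mapped to 1-based integers
#' in the order of `manifest$classes`.
#'
#' @param manifest a `modse2_manifest`.
#' @param preprocess_cfg optional [preprocess_config()]; `NULL` loads raw.
#' @return a dataset list `(task, x, y, classes)`.
#' @export
as_dataset <- function(manifest, preprocess_cfg = NULL) {
  rows <- manifest$rows
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(manifest$base, p))
  imgs <- lapply(seq_len(nrow(rows)), function(i) {
    im <- read_image(resolve(rows$image[i]))
    if (!is.null(preprocess_cfg)) im <- preprocess(im, preprocess_cfg)
    im
  })
  H <- dim(imgs[[1]])[1]; W <- dim(imgs[[1]])[2]
  x <- array(0, c(H, W, 1L, nrow(rows)))
  for (i in seq_along(imgs)) x[, , 1, i] <- imgs[[i]][, , 1]
  if (manifest$kind == "cls") {
    lab <- match(rows$label, manifest$classes)
    if (anyNA(lab)) {
      stopf("label '%s' outside the class mapping (allowed: %s)",
            rows$label[which(is.na(lab))[1]],
            paste(manifest$classes, collapse = ", "))
    }
    list(task = "cls", x = x, y = lab, classes = manifest$classes)
  } else {
    y <- array(0, c(H, W, 1L, nrow(rows)))
    for (i in seq_len(nrow(rows))) {
      m <- read_image(resolve(rows$mask[i]))[, , 1]
      y[, , 1, i] <- (m >= 0.5) * 1
    }
    list(task = "seg", x = x, y = y)
  }
}
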