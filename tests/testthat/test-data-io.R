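# Image IO, preprocessing and augmentation.  All fixtures are generated at
# test time (PNG via the package writer, NIfTI via RNifti).

test_that("PNG round trip is exact to 8-bit quantization; range mapping holds", {
  f <- tempfile(fileext = ".png")
  write_image_png(matrix(1, 5, 7), f)
  ones <- read_image(f)
  expect_equal(dim(ones), c(5L, 7L, 1L))
  expect_true(all(ones == 1))

  set.seed(8)
  img <- matrix(runif(15 * 11), 15, 11)
  write_image_png(img, f)
  back <- read_image(f)
  expect_lte(max(abs(back[, , 1] - img)), 1 / (2 * 255) + 1e-12)

  expect_error(read_image("no/such/file.png"), "not found")
  fj <- tempfile(fileext = ".jpg"); file.create(fj)
  expect_error(read_image(fj), "JPEG")
  fx <- tempfile(fileext = ".xyz"); file.create(fx)
  expect_error(read_image(fx), "unrecognized")
})

test_that("NIfTI volumes: slice extraction and lossless round trip", {
  vol <- array(seq(0, 1, length.out = 4 * 4 * 3), c(4, 4, 3))
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), f)
  sl <- read_image(f, nifti_slice = 3)
  ref <- vol[, , 3]
  ref <- (ref - min(ref)) / (max(ref) - min(ref))
  expect_maxabs(sl[, , 1], ref, 1e-6)
  expect_error(read_image(f, nifti_slice = 9), "out of range")
  expect_error(read_image(f), "slice index")
})

test_that("histogram equalization: hand CDF, identity on constants, uniformity", {
  v <- array(c(0, 1 / 3, 2 / 3, 1), c(2, 2, 1))
  eq <- hist_equalize(v, nbins = 4)
  expect_equal(sort(as.vector(eq)), c(0.25, 0.5, 0.75, 1.0))

  const <- array(0.4, c(3, 3, 1))
  expect_identical(hist_equalize(const), const)

  set.seed(9)
  img <- array(rbeta(64 * 64, 2, 5), c(64, 64, 1))  # skewed intensities
  eq <- hist_equalize(img)
  h <- tabulate(pmin(pmax(ceiling(as.vector(eq) * 16), 1), 16), 16)
  expect_lt(max(h) / min(h), 1.5)
})

test_that("preprocess: extent contract, [0,1] range, determinism", {
  set.seed(10)
  img <- array(runif(40 * 30), c(40, 30, 1))
  cfg <- preprocess_config(target = 32)
  out <- preprocess(img, cfg)
  expect_equal(dim(out), c(32L, 32L, 1L))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(preprocess(img, cfg), out)
  expect_error(preprocess(array(0, c(0, 4, 1)), cfg), "zero-sized")
})

test_that("augmentation: disabled passthrough, bounded draws, joint transform", {
  img <- array(runif(32 * 32), c(32, 32, 1))
  mask <- matrix(0, 32, 32); mask[10:20, 12:22] <- 1
  off <- preprocess_config(augment = FALSE)
  a0 <- augment(img, mask, off)
  expect_identical(a0$img, img)
  expect_identical(a0$mask, mask)

  angles <- numeric(20); scales <- numeric(20); areas <- numeric(20)
  for (s in 1:20) {
    cfg <- preprocess_config(augment = TRUE, seed = s)
    a <- augment(img, mask, cfg)
    angles[s] <- a$angle; scales[s] <- a$scale
    areas[s] <- sum(a$mask)
    expect_true(all(a$mask %in% c(0, 1)))
  }
  expect_true(all(abs(angles) <= 15))
  expect_true(all(scales >= 0.9 & scales <= 1.1))
  expect_gt(length(unique(angles)), 10)  # different seeds draw differently
  # mask survives the joint transform: area change bounded by scaling plus
  # interpolation loss
  expect_true(all(abs(areas / sum(mask) - 1) < 0.3))
  # reproducibility under a fixed seed
  cfg <- preprocess_config(augment = TRUE, seed = 3)
  expect_identical(augment(img, mask, cfg), augment(img, mask, cfg))
})

test_that("manifests: round trip, missing files, label mapping errors", {
  dir <- tempfile("ds"); dir.create(dir)
  for (i in 1:4) write_image_png(matrix(runif(16), 4), file.path(dir, sprintf("i%d.png", i)))
  rows <- data.frame(image = sprintf("i%d.png", 1:4),
                     label = c("a", "b", "a", "b"))
  mf <- file.path(dir, "manifest.csv")
  write_manifest(rows, mf)
  man <- load_manifest(mf)
  expect_equal(man$kind, "cls")
  expect_equal(man$classes, c("a", "b"))
  expect_equal(man$rows, rows)

  ds <- as_dataset(man)
  expect_equal(dim(ds$x), c(4L, 4L, 1L, 4L))
  expect_equal(ds$y, c(1L, 2L, 1L, 2L))

  rows_bad <- rbind(rows, data.frame(image = "missing.png", label = "a"))
  write_manifest(rows_bad, mf)
  expect_error(load_manifest(mf), "row 5")

  rows_dup <- rows; rows_dup$image[2] <- "i1.png"
  write_manifest(rows_dup, mf)
  expect_error(load_manifest(mf), "duplicate")
})
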