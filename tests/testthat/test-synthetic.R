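# Synthetic generators: determinism, construction guarantees, and the
# cross-validation of generator pose conventions against the group action.

test_that("classification set: determinism, balance, intensity offsets", {
  spec <- synthetic_spec("cls", n_samples = 100, extent = 32, seed = 3,
                         sigma = 0.1)
  a <- gen_classification_set(spec)
  b <- gen_classification_set(spec)
  expect_identical(a, b)
  expect_equal(as.vector(table(a$y)), rep(20L, 5L))
  expect_true(all(a$x >= 0 & a$x <= 1))

  # noiseless upright mode: stamped region brighter than background by the
  # configured offset
  s0 <- synthetic_spec("cls", n_samples = 10, extent = 32, seed = 4,
                       sigma = 0, rotate = FALSE, jitter = 0)
  d0 <- gen_classification_set(s0)
  for (i in 1:10) {
    img <- d0$x[, , 1, i]
    fg <- img[img > s0$background + s0$offset / 2]
    bg <- img[img <= s0$background + s0$offset / 2]
    expect_equal(mean(fg) - mean(bg), s0$offset, tolerance = 1e-9)
  }
})

test_that("segmentation set: masks are exactly the rendered support", {
  spec <- synthetic_spec("seg", n_samples = 12, extent = 32, seed = 5)
  d <- gen_segmentation_set(spec)
  expect_identical(d, gen_segmentation_set(spec))
  expect_true(all(d$y %in% c(0, 1)))
  expect_true(all(vapply(seq_len(12), function(i) sum(d$y[, , 1, i]) > 0, TRUE)))

  # noiseless twin: mask pixels are exactly those that received the offset
  s0 <- spec; s0$sigma <- 0
  d0 <- gen_segmentation_set(s0)
  for (i in 1:12) {
    img <- d0$x[, , 1, i]; msk <- d0$y[, , 1, i]
    expect_true(all(img[msk == 1] == s0$background + s0$offset))
    expect_true(all(img[msk == 0] == s0$background))
  }

  # foreground/background contrast close to the offset under noise
  fg <- mean(d$x[d$y == 1]); bg <- mean(d$x[d$y == 0])
  expect_equal(fg - bg, spec$offset, tolerance = 3 * spec$sigma / sqrt(100))
})

test_that("fine-scale set: exact areas, configured sides, contrast", {
  spec <- synthetic_spec("finescale", n_samples = 100, extent = 64, seed = 6)
  d <- gen_finescale_set(spec)
  expect_identical(d, gen_finescale_set(spec))
  for (i in 1:100) {
    expect_equal(sum(d$y[, , 1, i]), d$meta$side[i]^2)
  }
  expect_setequal(unique(d$meta$side), c(3L, 5L, 7L, 9L))
  expect_gt(mean(d$x[d$y == 1]) - mean(d$x[d$y == 0]), 0.4)
  expect_error(synthetic_spec("finescale", extent = 16, sides = c(3, 9)),
               "side lengths")
})

test_that("generator pose convention agrees with the group action", {
  # rotating an upright render by the group action reproduces the
  # generator's own rotated render of the same shape, up to boundary
  # interpolation
  for (shape in c("square", "cross", "triangle")) {
    up <- modse2:::render_shape(shape, 41, 11, 0, 0, 0)
    for (ang in c(pi / 2, pi / 4, 1.1)) {
      gen_rot <- modse2:::render_shape(shape, 41, 11, ang, 0, 0)
      act_rot <- act_on_image(
        se2_element(round(ang / (2 * pi / 64)) %% 64, c(0, 0), 64),
        up * 1, "bilinear") >= 0.5
      inter <- sum(gen_rot & act_rot)
      uni <- sum(gen_rot | act_rot)
      # quarter turns agree exactly; off-grid angles lose boundary pixels to
      # rasterization (worst for the thin-armed cross)
      expect_gt(inter / uni, if (abs(ang %% (pi / 2)) < 1e-9) 0.999 else 0.75)
    }
  }
})

test_that("datasets write to disk in a form the IO layer reads back", {
  spec <- synthetic_spec("seg", n_samples = 3, extent = 16, seed = 7)
  d <- gen_segmentation_set(spec)
  dir <- tempfile("segds")
  write_dataset(d, dir)
  man <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man$kind, "seg")
  ds <- as_dataset(man)
  expect_equal(dim(ds$x), dim(d$x))
  expect_identical(ds$y, d$y)  # binary masks survive 8-bit PNG exactly
  side <- jsonlite::read_json(file.path(dir, "dataset.json"))
  expect_equal(side$spec$n_samples, 3)
})
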