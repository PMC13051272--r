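test_that("mask and image PNGs round-trip exactly", {
  s <- generate_scene(tiny_scene_params(), seed = 4)
  d <- withr::local_tempdir()
  write_dataset(list(s), d, viz = TRUE)
  r <- read_dataset(d)[[1]]
  expect_identical(r$mask, s$mask)
  expect_equal(r$image, s$image)
  viz <- png::readPNG(file.path(d, "masks_viz", paste0(s$id, ".png")))
  expect_true(all(viz %in% c(0, 1)))  # 0/255 rendering on the [0,1] scale
})

test_that("labelme polygons rasterize by pixel-center point-in-polygon", {
  d <- withr::local_tempdir()
  png::writePNG(array(0.5, c(32, 32, 3)), file.path(d, "img.png"))
  doc <- list(imageHeight = 32L, imageWidth = 32L, imagePath = "img.png",
              shapes = list(
                list(label = "fagus",
                     points = list(c(10, 10), c(20, 10), c(20, 20), c(10, 20))),
                list(label = "rock",
                     points = list(c(1, 1), c(5, 1), c(5, 5), c(1, 5)))))
  jsonlite::write_json(doc, file.path(d, "ann.json"), auto_unbox = TRUE)
  s <- load_labelme(file.path(d, "ann.json"), "fagus")
  # brute-force count: centers with 10 <= x <= 20 and 10 <= y <= 20
  # (boundary included) -> 11 x 11 pixels
  expect_identical(sum(s$mask), 121)
  # only the matching label contributes: the rock square stays background
  expect_identical(sum(s$mask[1:6, 1:6]), 0)
  # zero shapes -> all-zero mask
  doc$shapes <- list()
  jsonlite::write_json(doc, file.path(d, "empty.json"), auto_unbox = TRUE)
  expect_true(all(load_labelme(file.path(d, "empty.json"), "fagus")$mask == 0))
  # malformed polygon -> format error naming the shape
  doc$shapes <- list(list(label = "fagus", points = list(c(1, 1), c(2, 2))))
  jsonlite::write_json(doc, file.path(d, "bad.json"), auto_unbox = TRUE)
  expect_error(load_labelme(file.path(d, "bad.json"), "fagus"),
               class = "canopyseg_format_error")
})

test_that("resizing treats image and mask by their own interpolation rules", {
  m4 <- matrix(0, 4, 4); m4[2:3, 2:3] <- 1
  s <- new_sample(array(100, c(4, 4, 3)), m4, "x")
  r <- resize_sample(s, 8)
  # nearest-neighbour index map doubles every source pixel: 4 -> 16 ones
  expect_identical(sum(r$mask), 16)
  expect_true(all(r$mask %in% c(0, 1)))
  # identity size is a no-op; constant masks stay constant
  s16 <- rand_sample(16, 16)
  expect_identical(resize_sample(s16, 16), s16)
  ones <- new_sample(rand_image(16, 16), matrix(1, 16, 16), "o")
  expect_true(all(resize_sample(ones, 32)$mask == 1))
  expect_error(resize_sample(s, 4.5), class = "canopyseg_param_error")
})

test_that("splitting uses round-half-away sizes and is a seeded partition", {
  mk <- function(n) lapply(seq_len(n), function(i)
    new_sample(array(0, c(32, 32, 3)), matrix(0, 32, 32), sprintf("s%04d", i)))
  sp <- split_dataset(mk(10), 0.8, seed = 5)
  expect_length(sp$train, 8)
  expect_length(sp$val, 2)
  sp2 <- split_dataset(mk(10), 0.8, seed = 5)
  expect_identical(vapply(sp$train, `[[`, "", "id"),
                   vapply(sp2$train, `[[`, "", "id"))
  # the published 4510-id case: round(0.8 * 4510) = 3608 / 902
  expect_identical(round(canopyseg:::round_half_away(0.8 * 4510)), 3608)
  # partition property over many n
  for (n in c(1:10, 25, 50)) {
    sp <- split_dataset(mk(n), 0.8, seed = n)
    ids <- c(vapply(sp$train, `[[`, "", "id"), vapply(sp$val, `[[`, "", "id"))
    expect_setequal(ids, sprintf("s%04d", seq_len(n)))
    expect_identical(anyDuplicated(ids), 0L)
  }
})

test_that("augmented provenance cannot enter a split", {
  s <- list(rand_sample(32, 32, "a"),
            new_sample(rand_image(32, 32), rand_mask(32, 32), "b",
                       "classic_aug"))
  expect_error(split_dataset(s, 0.5, 1), class = "canopyseg_leakage_error")
  expect_error(split_dataset(list(rand_sample(32, 32)), 0, 1),
               class = "canopyseg_param_error")
})
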