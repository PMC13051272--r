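test_that("flips are involutions and rotations form the cyclic group", {
  s <- rand_sample(16, 16)
  fh <- classic_aug_spec("flip_h"); fv <- classic_aug_spec("flip_v")
  twice <- geometric_transform(geometric_transform(s, fh), fh)
  expect_equal(twice$image, s$image)
  expect_identical(twice$mask, s$mask)
  twice <- geometric_transform(geometric_transform(s, fv), fv)
  expect_equal(twice$image, s$image)

  r90 <- classic_aug_spec("rotate", rotate_angles = 90)
  four <- s
  for (i in 1:4) four <- geometric_transform(four, r90)
  expect_equal(four$image, s$image)
  expect_identical(four$mask, s$mask)
})

test_that("a 90-degree rotation maps (r, c) to (c, N-1-r) for every pixel", {
  N <- 8
  spec <- classic_aug_spec("rotate", rotate_angles = 90)
  for (r in 0:(N - 1)) for (c in 0:(N - 1)) {
    m <- matrix(0, N, N); m[r + 1, c + 1] <- 1
    s <- new_sample(array(0, c(N, N, 3)), m, "px")
    out <- geometric_transform(s, spec)$mask
    expect_equal(which(out == 1) - 1L,
                 c + N * (N - 1 - r))  # 0-based column-major index
  }
})

test_that("geometric and pixel kinds are mutually exclusive contracts", {
  s <- rand_sample(16, 16)
  expect_error(geometric_transform(s, classic_aug_spec("gauss_noise")),
               class = "canopyseg_contract_error")
  expect_error(pixel_perturb(s, classic_aug_spec("flip_h")),
               class = "canopyseg_contract_error")
})

test_that("pixel perturbations leave the mask byte-identical and clip", {
  s <- rand_sample(32, 32)
  for (k in c("gauss_noise", "gauss_blur", "contrast")) {
    out <- pixel_perturb(s, classic_aug_spec(k), seed = 9)
    expect_identical(out$mask, s$mask)
    expect_true(all(out$image >= 0 & out$image <= 255))
    expect_identical(dim(out$image), dim(s$image))
    expect_identical(out$provenance, "classic_aug")
  }
})

test_that("zero noise is the identity and contrast fixes the mean", {
  s <- rand_sample(16, 16)
  out <- pixel_perturb(s, classic_aug_spec("gauss_noise",
                                           noise_sigma = c(0, 0)), seed = 1)
  expect_equal(out$image, s$image)
  # constant image at its own mean: (v - m) * f + m = v for any factor
  const <- new_sample(array(120, c(16, 16, 3)), rand_mask(16, 16), "c")
  out <- pixel_perturb(const, classic_aug_spec("contrast"), seed = 2)
  expect_equal(out$image, const$image)
})

test_that("arbitrary-angle rotation is gated and re-binarizes the mask", {
  s <- rand_sample(32, 32)
  expect_error(geometric_transform(
    s, classic_aug_spec("rotate", rotate_angles = 33)),
    class = "canopyseg_param_error")
  out <- geometric_transform(
    s, classic_aug_spec("rotate", rotate_angles = 33,
                        arbitrary_rotation = TRUE))
  expect_true(all(out$mask %in% c(0, 1)))
  expect_true(all(out$image >= 0 & out$image <= 255))
})

test_that("the classic pipeline is seeded and mask-consistent", {
  base <- lapply(1:3, function(i) {
    s <- generate_scene(tiny_scene_params(), seed = i); s$id <- paste0("b", i); s
  })
  a1 <- augment_classic(base, mult = 2, seed = 11)
  a2 <- augment_classic(base, mult = 2, seed = 11)
  expect_length(a1, 9)
  for (i in seq_along(a1)) expect_identical(a1[[i]]$image, a2[[i]]$image)
  gen <- a1[-(1:3)]
  expect_true(all(vapply(gen, `[[`, "", "provenance") == "classic_aug"))
  for (g in gen) expect_true(all(g$mask %in% c(0, 1)))
  a3 <- augment_classic(base, mult = 2, seed = 12)
  expect_false(all(mapply(function(x, y) identical(x$image, y$image),
                          a1[-(1:3)], a3[-(1:3)])))
})
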