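test_that("fog blending reproduces the per-pixel transform exactly", {
  # single pixel: 0.5 * 100 + 0.5 * 230 = 165
  expect_equal(fog_blend(array(100, c(1, 1, 3)),
                         matrix(0.5, 1, 1), 230)[1, 1, 1], 165)
  # zero opacity field is the identity
  img <- rand_image(40, 50)
  expect_equal(fog_blend(img, matrix(0, 40, 50), 230), img)
  f <- simulate_fog(img, fog_params(alpha_peak = c(0, 0)), seed = 2)
  expect_equal(f, img)
  # convex combination: every output between input value and fog colour
  M <- matrix(stats::runif(40 * 50), 40, 50)
  fb <- fog_blend(img, M, 237)
  expect_true(all(fb >= pmin(img, 237) - 1e-9 & fb <= pmax(img, 237) + 1e-9))
})

test_that("overexposure is pixel-wise non-decreasing and clips at 255", {
  expect_equal(overexpose_blend(array(200, c(1, 1, 3)),
                                matrix(0.5, 1, 1), 200)[1, 1, 1], 255)
  img <- rand_image(40, 40)
  expect_equal(overexpose_blend(img, matrix(0, 40, 40), 180), img)
  out <- simulate_overexposure(img, seed = 4)
  expect_true(all(out >= img - 1e-9))
  expect_true(all(out <= 255))
})

test_that("motion-blur kernels are unit-sum rotated lines", {
  for (L in c(5, 9, 21, 31)) for (th in c(0, 17.3, 45, 90, 121.8, 179)) {
    p <- motion_psf(L, th)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  # even lengths round up to odd
  expect_identical(dim(motion_psf(6, 0)), c(7L, 7L))
  expect_error(motion_psf(0), class = "canopyseg_param_error")
  # theta = 0, L = 3 on a horizontal ramp: interior = mean of 3 neighbours
  ramp <- matrix(rep(c(0, 90, 180), each = 3), 3, 3)
  b <- canopyseg:::conv2_reflect(ramp, motion_psf(3, 0))
  expect_equal(b[2, 2], 90)
})

test_that("motion blur blends, preserves constants, and gamma=0 is identity", {
  img <- rand_image(48, 48)
  expect_equal(motion_blur_apply(img, motion_psf(9, 30), 0), img)
  const <- array(77, c(40, 40, 3))
  out <- motion_blur_apply(const, motion_psf(31, 63), 1)
  expect_equal(max(abs(out - 77)), 0, tolerance = 1e-9)
  out <- simulate_motion_blur(img, seed = 8)
  expect_true(all(out >= 0 & out <= 255))
})

test_that("mean brightness is preserved by full-strength blur on reflect pads", {
  img <- rand_image(64, 64)
  out <- motion_blur_apply(img, motion_psf(15, 40), 1)
  expect_lt(abs(mean(out) - mean(img)), 0.5)
})

test_that("occlusion rewrites exactly S^2 pixels in all channels", {
  # image values strictly above the fill so every written pixel differs
  s <- new_sample(array(floor(runif(64 * 80 * 3, 1, 256)), c(64, 80, 3)),
                  rand_mask(64, 80), "s")
  out <- simulate_occlusion(s, occlusion_params(size = 50, fill = 0), seed = 3)
  changed <- out$image != s$image
  patch <- apply(changed, c(1, 2), any)
  expect_identical(sum(patch), 2500L)
  expect_true(all(out$image[patch] == 0))  # all channels at the fill value
  expect_identical(out$mask, s$mask)
  expect_identical(out$provenance, "esref_aug")
  small <- rand_sample(32, 32)
  expect_error(simulate_occlusion(small, occlusion_params(size = 50)),
               class = "canopyseg_param_error")
})

test_that("all four simulators are pure functions of (input, params, seed)", {
  img <- rand_image(48, 48)
  s <- new_sample(img, rand_mask(48, 48), "d")
  expect_identical(simulate_fog(img, seed = 5), simulate_fog(img, seed = 5))
  expect_identical(simulate_overexposure(img, seed = 5),
                   simulate_overexposure(img, seed = 5))
  expect_identical(simulate_motion_blur(img, seed = 5),
                   simulate_motion_blur(img, seed = 5))
  expect_identical(simulate_occlusion(s, occlusion_params(20), seed = 5)$image,
                   simulate_occlusion(s, occlusion_params(20), seed = 5)$image)
})

test_that("sampled parameters stay inside their configured ranges", {
  set.seed(31)
  for (i in 1:200) {
    fd <- fog_draw(fog_params(), 100, 100)
    expect_true(all(fd$peaks >= 0.4 & fd$peaks <= 0.8))
    expect_true(fd$fog_color >= 220 && fd$fog_color <= 245)
    expect_true(fd$n >= 1 && fd$n <= 3)
    od <- overexposure_draw(overexposure_params(), 100, 100)
    expect_true(od$alpha >= 0.5 && od$alpha <= 0.9)
    expect_true(od$beta >= 150 && od$beta <= 255)
    md <- motion_blur_draw(motion_blur_params())
    expect_true(md$length >= 5 && md$length <= 32 && md$length %% 2 == 1)
    expect_true(md$theta >= 0 && md$theta < 180)
    expect_true(md$gamma >= 0.35 && md$gamma <= 0.8)
  }
})

test_that("dataset expansion counts, tags and reproduces deterministically", {
  train <- lapply(1:5, function(i) {
    s <- generate_scene(tiny_scene_params(), seed = i)
    s$id <- paste0("t", i); s
  })
  none <- expand_esref(train, plan = list(), seed = 1)
  expect_identical(none, train)
  one <- expand_esref(train, plan = list(motion = 3L), seed = 1)
  expect_length(one, 20)  # n * (1 + 3)
  full <- expand_esref(train, seed = 7)
  expect_length(full, 25)
  full2 <- expand_esref(train, seed = 7)
  for (i in seq_along(full)) {
    expect_identical(full[[i]]$image, full2[[i]]$image)
    expect_identical(full[[i]]$mask, full2[[i]]$mask)
  }
  gen <- full[-(1:5)]
  expect_true(all(vapply(gen, `[[`, "", "provenance") == "esref_aug"))
  # masks ride along untouched
  for (i in 1:5) expect_identical(gen[[i]]$mask, train[[i]]$mask)
  # environment-augmented input is rejected (leakage guard)
  expect_error(expand_esref(gen[1]), class = "canopyseg_leakage_error")
})
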