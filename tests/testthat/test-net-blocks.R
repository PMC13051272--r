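test_that("split convolution matches the dense branch-equation oracle", {
  set.seed(101)
  for (i in 1:50) {
    L <- sample(c(4L, 8L, 12L, 16L), 1)
    M <- sample(c(2L, 4L, 6L, 8L), 1)
    H <- sample(2:6, 1); W <- sample(2:6, 1)
    cfg <- spconv_config(L, M)
    w <- spconv_init(cfg)
    x <- rand_fmap(H, W, L)
    got <- spconv_forward(x, cfg, w)
    expect_equal(unclass(got), oracle_spconv(x, cfg, w),
                 tolerance = 1e-5, ignore_attr = TRUE)
    expect_identical(dim(got)[1:2], dim(x)[1:2])  # H x W preserved
  }
})

test_that("split-convolution fusion weights sum to one per channel", {
  cfg <- spconv_config(8L, 4L)
  w <- spconv_init(cfg, seed = 2)
  out <- spconv_forward(rand_fmap(5, 5, 8), cfg, w)
  beta <- attr(out, "fusion_beta")
  expect_length(beta, 4)
  expect_equal(beta + (1 - beta), rep(1, 4))
  expect_true(all(beta > 0 & beta < 1))
})

test_that("all-zero split-convolution weights give an all-zero output", {
  cfg <- spconv_config(4L, 2L)
  w <- spconv_init(cfg, seed = 1)
  w <- lapply(w, function(a) a * 0)
  out <- spconv_forward(rand_fmap(3, 3, 4), cfg, w)
  expect_true(all(out == 0))
})

test_that("split-convolution parameter counts follow the closed form", {
  # L = M = 64, alpha = 1/2, G = 2, k = 3: 9216 + 2048 + 2048
  expect_identical(spconv_param_count(spconv_config(64L, 64L)), 13312L)
  # strictly below the vanilla 3x3 count for all tested configs
  for (L in 2^(2:8)) for (M in 2^(2:8)) {
    cfg <- spconv_config(L, M)
    expect_lt(spconv_param_count(cfg), L * M * 9)
  }
  # degenerate limit: groups = 1 on the representative half
  cfg <- spconv_config(8L, 4L, groups = 1L)
  expect_identical(spconv_param_count(cfg),
                   4L * 4L * 9L + 4L * 4L + 4L * 4L)
  # an odd representative count cannot satisfy the group constraint
  expect_error(spconv_config(2L, 2L), class = "canopyseg_config_error")
})

test_that("criss-cross attention matches the position-by-position oracle", {
  set.seed(202)
  for (i in 1:50) {
    C <- sample(c(2L, 4L, 8L), 1)
    H <- sample(2:6, 1); W <- sample(2:6, 1)
    w <- cca_init(C, proj_channels = max(1L, C %/% 2L))
    x <- rand_fmap(H, W, C)
    got <- cca_forward(x, w)
    expect_equal(unclass(got), oracle_cca(x, w),
                 tolerance = 1e-5, ignore_attr = TRUE)
    expect_identical(dim(got), dim(x))  # C and H x W preserved
    # attention map shape and normalization
    a <- attr(got, "attention")
    expect_identical(dim(a), c(H + W - 1L, H, W))
    expect_equal(apply(a, c(2, 3), sum), matrix(1, H, W), tolerance = 1e-6)
  }
})

test_that("criss-cross attention degenerates correctly", {
  # 1x1 map: softmax over one element is 1, output = value + input
  w <- cca_init(4L, 1L, seed = 3)
  x <- rand_fmap(1, 1, 4)
  got <- cca_forward(x, w)
  v <- drop(x[1, 1, ] %*% matrix(w$value, 4, 4))
  expect_equal(as.vector(got), v + as.vector(x), tolerance = 1e-10)
  # zero value projection leaves the residual only
  w$value <- w$value * 0
  x2 <- rand_fmap(4, 5, 4)
  expect_equal(unclass(cca_forward(x2, w)), x2,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(cca_init(4L, 4L), class = "canopyseg_config_error")
})

test_that("context-guided downsampling matches the sliding-window oracle", {
  set.seed(303)
  for (i in 1:50) {
    Cin <- sample(c(2L, 3L, 4L, 8L), 1)
    Cout <- sample(c(2L, 4L, 8L), 1)
    H <- 2L * sample(1:4, 1); W <- 2L * sample(1:4, 1)
    cfg <- cgb_config(Cin, Cout)
    w <- cgb_init(cfg)
    x <- rand_fmap(H, W, Cin)
    got <- cgb_down_forward(x, cfg, w)
    expect_equal(got, oracle_cgb(x, cfg, w), tolerance = 1e-5)
    expect_identical(dim(got), c(H %/% 2L, W %/% 2L, Cout))
  }
})

test_that("context-guided downsampling contracts and neutral scaling", {
  cfg <- cgb_config(64L, 128L)
  w <- cgb_init(cfg, seed = 5)
  out <- cgb_down_forward(rand_fmap(32, 32, 64), cfg, w)
  expect_identical(dim(out), c(16L, 16L, 128L))
  # forcing the global branch off returns the unscaled joint feature,
  # and all-ones channel weights reproduce it
  x <- rand_fmap(8, 8, 64)
  joint <- cgb_down_forward(x, cfg, w, glo = FALSE)
  w1 <- w; w1$mlp_w2 <- w$mlp_w2 * 0
  w1$mlp_b2 <- rep(1e9, cfg$out_channels)  # sigmoid -> 1
  expect_equal(cgb_down_forward(x, cfg, w1), joint, tolerance = 1e-9)
  expect_error(cgb_down_forward(rand_fmap(7, 8, 64), cfg, w),
               class = "canopyseg_contract_error")
  expect_error(cgb_config(4L, 5L), class = "canopyseg_config_error")
})

test_that("shape contracts hold across spatial sizes", {
  for (hw in c(2L, 4L, 8L, 16L, 32L)) {
    cfg <- spconv_config(4L, 6L)
    expect_identical(dim(spconv_forward(rand_fmap(hw, hw, 4),
                                        cfg, spconv_init(cfg, 1))),
                     c(hw, hw, 6L))
    expect_identical(dim(cca_forward(rand_fmap(hw, hw, 4), cca_init(4L, 2L, 1))),
                     c(hw, hw, 4L))
    ccfg <- cgb_config(4L, 8L)
    expect_identical(dim(cgb_down_forward(rand_fmap(hw, hw, 4),
                                          ccfg, cgb_init(ccfg, 1))),
                     c(hw %/% 2L, hw %/% 2L, 8L))
  }
})
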