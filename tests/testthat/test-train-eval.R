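test_that("cross-entropy has its closed-form values", {
  # certain prediction -> 0 loss
  l <- array(0, c(4, 4, 2))
  l[, , 2] <- 100
  expect_equal(cross_entropy_loss(l, matrix(1, 4, 4)), 0, tolerance = 1e-9)
  # uniform prediction -> ln 2 per pixel
  expect_equal(cross_entropy_loss(array(0, c(8, 8, 2)), rand_mask(8, 8)),
               log(2), tolerance = 1e-12)
  # single pixel with true-class probability 1/4 -> -ln(1/4)
  l <- array(c(log(3), log(1)), c(1, 1, 2))
  expect_equal(cross_entropy_loss(l, matrix(1, 1, 1)), -log(0.25),
               tolerance = 1e-12)
  expect_error(cross_entropy_loss(array(0, c(2, 2, 2)), matrix(2, 2, 2)))
})

test_that("confusion counts by the four-cell definitions", {
  m <- rand_mask(8, 8)
  cm <- confusion(m, m)
  expect_identical(cm$fp + cm$fn, 0L)
  cm <- confusion(1 - m, m)
  expect_identical(cm$tp + cm$tn, 0L)
  # hand-placed 4x4 pair: tp=3, fn=1, fp=2, tn=10
  truth <- matrix(0, 4, 4); truth[1, 1:4] <- 1
  pred <- matrix(0, 4, 4); pred[1, 1:3] <- 1; pred[2, 1:2] <- 1
  cm <- confusion(pred, truth)
  expect_identical(unlist(cm[c("tp", "fn", "fp", "tn")]),
                   c(tp = 3L, fn = 1L, fp = 2L, tn = 10L))
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "canopyseg_contract_error")
})

test_that("metrics match exact rational recomputation on random masks", {
  set.seed(17)
  for (i in 1:1000) {
    pred <- rand_mask(8, 8, p = runif(1, 0.05, 0.95))
    truth <- rand_mask(8, 8, p = runif(1, 0.05, 0.95))
    got <- compute_metrics(confusion(pred, truth))
    want <- oracle_metrics(pred, truth)
    expect_identical(got$miou, want$miou)
    expect_identical(got$pa, want$pa)
    expect_identical(got$mpa, want$mpa)
    expect_identical(got$mprecision, want$mprec)
    expect_identical(got$mrecall, want$mrec)
  }
})

test_that("worked metric case and degenerate conventions hold", {
  cm <- structure(list(tp = 3L, fn = 1L, fp = 2L, tn = 10L),
                  class = "confusion_matrix")
  m <- compute_metrics(cm)
  expect_equal(m$iou_per_class[["foreground"]], 0.5)
  expect_equal(m$iou_per_class[["background"]], 10 / 13)
  expect_equal(m$miou, (0.5 + 10 / 13) / 2)
  expect_equal(m$pa, 13 / 16)
  # perfect prediction -> all ones
  p <- compute_metrics(structure(list(tp = 5L, fn = 0L, fp = 0L, tn = 11L),
                                 class = "confusion_matrix"))
  expect_equal(p$miou, 1); expect_equal(p$mpa, 1)
  expect_equal(p$mprecision, 1); expect_equal(p$mrecall, 1)
  # absent foreground: empty-union class contributes identity 1
  a <- compute_metrics(structure(list(tp = 0L, fn = 0L, fp = 0L, tn = 9L),
                                 class = "confusion_matrix"))
  expect_equal(a$miou, 1)
  expect_true(a$absent_class[["foreground"]])
})

test_that("mPA is the per-class mean, not the global pixel accuracy", {
  # unequal class sizes separate the two definitions
  cm <- structure(list(tp = 1L, fn = 3L, fp = 0L, tn = 12L),
                  class = "confusion_matrix")
  m <- compute_metrics(cm)
  expect_equal(m$pa, 13 / 16)
  expect_equal(m$mpa, (1 / 4 + 1) / 2)
  expect_false(isTRUE(all.equal(m$mpa, m$pa)))
})

test_that("the cosine schedule hits its endpoints and decreases", {
  cfg <- train_config(lr0 = 1e-3, lr_min = 1e-9)
  expect_equal(cosine_lr(0, 100, cfg), 1e-3)
  expect_equal(cosine_lr(100, 100, cfg), 1e-5)  # ratio 0.01
  expect_equal(cosine_lr(50, 100, cfg), 1e-5 + 0.5 * (1e-3 - 1e-5))
  lrs <- cosine_lr(0:100, 100, cfg)
  expect_true(all(diff(lrs) <= 1e-15))
  # the reference defaults floor at lr_min
  expect_equal(cosine_lr(100, 100, train_config()), 1e-9)
  expect_error(cosine_lr(0, 0), class = "canopyseg_param_error")
  expect_error(cosine_lr(5, 4), class = "canopyseg_param_error")
})

test_that("training is deterministic and records history per epoch", {
  ds <- generate_dataset(2, tiny_scene_params(32), seed = 5)
  split <- split_dataset(ds, 0.5, seed = 1)
  cfg <- train_config(epochs = 1, image_size = 32, batch_size = 1,
                      lr0 = 1e-3, seed = 11)
  f1 <- train(build_model(model_spec(width = 1/16, seed = 3)), split, cfg)
  f2 <- train(build_model(model_spec(width = 1/16, seed = 3)), split, cfg)
  expect_identical(nrow(f1$history), 1L)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_s3_class(f1, "canopyseg_fit")
  expect_true(is.finite(f1$best$miou))
})

test_that("training aborts when augmented samples sit in the validation set", {
  ds <- generate_dataset(2, tiny_scene_params(32), seed = 5)
  split <- split_dataset(ds, 0.5, seed = 1)
  split$val[[1]]$provenance <- "esref_aug"
  expect_error(train(build_model(model_spec(width = 1/16, seed = 3)), split,
                     train_config(epochs = 1, image_size = 32)),
               class = "canopyseg_leakage_error")
})
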