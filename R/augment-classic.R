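# Classic augmentations with the strict mask-synchronization contract:
# geometric transforms move image and mask through the identical spatial
# map; pixel-level perturbations leave the mask byte-identical.

#' Classic augmentation specification
#'
#' Magnitude defaults are conservative: right-angle rotations are lossless
#' and mask-exact; noise/blur/contrast stay within what clear-day UAV
#' acquisitions plausibly show. All fields are overridable.
#'
#' @param kind one of `flip_h`, `flip_v`, `rotate`, `gauss_noise`,
#'   `gauss_blur`, `contrast`.
#' @param rotate_angles set of angles (degrees) drawn from for `rotate`.
#' @param noise_sigma grey-level range for the Gaussian noise sigma.
#' @param blur_kernel odd kernel sizes drawn from for Gaussian blur.
#' @param contrast_factor multiplicative range applied about the per-image
#'   mean.
#' @param apply_prob probability that each operation fires in the
#'   [augment_classic()] pipeline.
#' @param arbitrary_rotation allow non-right angles in `rotate_angles`
#'   (bilinear image / nearest mask resampling with reflect padding).
#' @return A `classic_aug_spec` list.
#' @export
classic_aug_spec <- function(kind = c("flip_h", "flip_v", "rotate",
                                      "gauss_noise", "gauss_blur", "contrast"),
                             rotate_angles = c(90, 180, 270),
                             noise_sigma = c(5, 15),
                             blur_kernel = c(3, 5),
                             contrast_factor = c(0.8, 1.5),
                             apply_prob = 0.5,
                             arbitrary_rotation = FALSE) {
  kind <- match.arg(kind)
  if (any(blur_kernel %% 2 != 1) || any(blur_kernel < 3))
    .err("blur kernels must be odd and >= 3", "canopyseg_param_error")
  if (any(noise_sigma < 0))
    .err("noise sigma must be non-negative", "canopyseg_param_error")
  if (apply_prob < 0 || apply_prob > 1)
    .err("apply_prob must lie in [0,1]", "canopyseg_param_error")
  structure(list(kind = kind, rotate_angles = rotate_angles,
                 noise_sigma = noise_sigma, blur_kernel = blur_kernel,
                 contrast_factor = contrast_factor, apply_prob = apply_prob,
                 arbitrary_rotation = arbitrary_rotation),
            class = "classic_aug_spec")
}

# Right-angle rotation of a plane: 0-based (r, c) -> (c, N-1-r) per 90 deg.
.rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])

.rot_right_angle <- function(m, angle) {
  for (i in seq_len((as.integer(angle) %/% 90L) %% 4L)) m <- .rot90(m)
  m
}

# Arbitrary-angle rotation about the image center by inverse mapping.
.rot_any <- function(m, angle, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H) - cy, H, W)
  c <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  sr <- cos(th) * r - sin(th) * c + cy
  sc <- sin(th) * r + cos(th) * c + cx
  refl <- function(i, n) {  # reflect out-of-range coordinates
    i <- abs(i - 1) %% (2 * (n - 1))
    pmin(i, 2 * (n - 1) - i) + 1
  }
  if (interp == "nearest") {
    ri <- refl(round(sr), H); ci <- refl(round(sc), W)
    matrix(m[cbind(as.vector(ri), as.vector(ci))], H, W)
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    gv <- function(ri, ci) matrix(m[cbind(as.vector(refl(ri, H)),
                                          as.vector(refl(ci, W)))], H, W)
    (1 - fr) * (1 - fc) * gv(r0, c0) + fr * (1 - fc) * gv(r0 + 1, c0) +
      (1 - fr) * fc * gv(r0, c0 + 1) + fr * fc * gv(r0 + 1, c0 + 1)
  }
}

.apply_planes <- function(image, f) {
  planes <- lapply(1:3, function(c) f(image[, , c]))
  array(unlist(planes), c(dim(planes[[1]]), 3))
}

#' Geometric augmentation (mask follows the image)
#'
#' Flips and rotations; the mask receives the identical spatial map and is
#' re-binarized, so label-pixel correspondence is exact.
#'
#' @param sample a [new_sample()] object.
#' @param spec a [classic_aug_spec()] with a geometric `kind`.
#' @param seed integer seed for the angle draw.
#' @return Transformed sample with provenance `"classic_aug"`.
#' @export
geometric_transform <- function(sample, spec, seed = NULL) {
  if (!spec$kind %in% c("flip_h", "flip_v", "rotate"))
    .err("geometric_transform requires a geometric kind",
         "canopyseg_contract_error")
  img <- sample$image; mask <- sample$mask
  if (spec$kind == "flip_h") {
    img <- img[, ncol(mask):1, , drop = FALSE]
    mask <- mask[, ncol(mask):1, drop = FALSE]
  } else if (spec$kind == "flip_v") {
    img <- img[nrow(mask):1, , , drop = FALSE]
    mask <- mask[nrow(mask):1, , drop = FALSE]
  } else {
    angle <- with_seed(seed, {
      a <- spec$rotate_angles
      if (length(a) > 1) sample(a, 1) else a
    })
    if (angle %% 90 == 0) {
      img <- .apply_planes(img, function(p) .rot_right_angle(p, angle))
      mask <- .rot_right_angle(mask, angle)
    } else {
      if (!spec$arbitrary_rotation)
        .err("non-right angle requires arbitrary_rotation = TRUE",
             "canopyseg_param_error")
      img <- clip255(round(.apply_planes(img, function(p)
        .rot_any(p, angle, "bilinear"))))
      mask <- (.rot_any(mask, angle, "nearest") >= 0.5) * 1
    }
  }
  new_sample(img, mask, sample$id, "classic_aug")
}

#' Pixel-level augmentation (mask untouched)
#'
#' Gaussian noise, Gaussian blur or contrast adjustment about the per-image
#' mean. The output image is clipped to `[0, 255]`; the mask is returned
#' byte-identical to the input.
#'
#' @inheritParams geometric_transform
#' @param spec a [classic_aug_spec()] with a pixel-level `kind`.
#' @export
pixel_perturb <- function(sample, spec, seed = NULL) {
  if (!spec$kind %in% c("gauss_noise", "gauss_blur", "contrast"))
    .err("pixel_perturb requires a pixel-level kind",
         "canopyseg_contract_error")
  img <- with_seed(seed, {
    if (spec$kind == "gauss_noise") {
      sg <- stats::runif(1, spec$noise_sigma[1],
                         spec$noise_sigma[length(spec$noise_sigma)])
      sample$image + if (sg > 0) stats::rnorm(length(sample$image), 0, sg) else 0
    } else if (spec$kind == "gauss_blur") {
      k <- if (length(spec$blur_kernel) > 1) sample(spec$blur_kernel, 1)
      else spec$blur_kernel
      kern <- gaussian_kernel(k)
      .apply_planes(sample$image, function(p) conv2_reflect(p, kern))
    } else {
      f <- stats::runif(1, spec$contrast_factor[1],
                        spec$contrast_factor[length(spec$contrast_factor)])
      m <- mean(sample$image)
      (sample$image - m) * f + m
    }
  })
  new_sample(clip255(round(img)), sample$mask, sample$id, "classic_aug")
}

#' Classic augmentation pipeline
#'
#' For each input sample generates `mult` augmented copies; within a copy
#' each operation fires independently with `apply_prob` (flips/rotation
#' first, then pixel-level perturbations). Deterministic under `seed`.
#'
#' @param samples list of [new_sample()] objects.
#' @param mult augmented copies per input sample.
#' @param seed integer seed.
#' @param apply_prob per-operation firing probability.
#' @return The input samples followed by the generated ones.
#' @export
augment_classic <- function(samples, mult = 1L, seed = 11L, apply_prob = 0.5) {
  if (mult < 0) .err("mult must be >= 0", "canopyseg_param_error")
  kinds <- c("flip_h", "flip_v", "rotate", "gauss_noise", "gauss_blur",
             "contrast")
  out <- with_seed(seed, {
    gen <- list()
    for (m in seq_len(mult)) {
      for (s in samples) {
        a <- s
        for (k in kinds) {
          if (stats::runif(1) >= apply_prob) next
          spec <- classic_aug_spec(kind = k, apply_prob = apply_prob)
          a <- if (k %in% c("flip_h", "flip_v", "rotate"))
            geometric_transform(a, spec, seed = NULL)
          else pixel_perturb(a, spec, seed = NULL)
        }
        a$id <- sprintf("%s_classic%02d", s$id, m)
        a$provenance <- "classic_aug"
        gen[[length(gen) + 1L]] <- a
      }
    }
    gen
  })
  c(samples, out)
}
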