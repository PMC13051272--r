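# Environment-simulation augmentation: four degradation simulators (fog,
# local overexposure, directional motion blur, occlusion) that reproduce
# the dominant field-acquisition disturbances of UAV forestry imagery, plus
# the dataset-expansion planner. All four are pixel-level operations: the
# mask is never altered. Each application draws fresh parameters from the
# configured ranges, and everything is a pure function of
# (input, params, seed).

#' Fog simulation parameters
#'
#' Haze is approximated by blending the image towards a bright grey fog
#' colour through a smooth local opacity field built from `n_spots`
#' Gaussian-smoothed circular spots.
#'
#' @param alpha_peak range of the per-spot peak opacity.
#' @param fog_color grey-level range of the fog colour (applied to all
#'   three channels).
#' @param radius_frac spot radius as a fraction of `min(H, W)`.
#' @param kernel_frac Gaussian kernel size as a fraction of the spot radius
#'   (rounded to the nearest odd integer >= 3).
#' @param n_spots integer range for the number of fog spots.
#' @return A `fog_params` list.
#' @export
fog_params <- function(alpha_peak = c(0.4, 0.8), fog_color = c(220, 245),
                       radius_frac = 0.3, kernel_frac = 0.7,
                       n_spots = c(1L, 3L)) {
  if (any(alpha_peak < 0) || any(alpha_peak > 1))
    .err("alpha_peak must lie in [0,1]", "canopyseg_param_error")
  if (any(n_spots < 1)) .err("n_spots must be >= 1", "canopyseg_param_error")
  structure(list(alpha_peak = alpha_peak, fog_color = fog_color,
                 radius_frac = radius_frac, kernel_frac = kernel_frac,
                 n_spots = as.integer(n_spots)),
            class = "fog_params")
}

#' Local overexposure parameters
#'
#' @param alpha range of the initial mask opacity of the highlight spot.
#' @param beta range of the maximum brightness increment (grey levels).
#' @param radius_frac highlight radius as a fraction of `min(H, W)`.
#' @param kernel_frac Gaussian kernel size as a fraction of the radius.
#' @return An `overexposure_params` list.
#' @export
overexposure_params <- function(alpha = c(0.5, 0.9), beta = c(150, 255),
                                radius_frac = 0.25, kernel_frac = 1.5) {
  structure(list(alpha = alpha, beta = beta, radius_frac = radius_frac,
                 kernel_frac = kernel_frac),
            class = "overexposure_params")
}

#' Directional motion-blur parameters
#'
#' @param length pixel range of the linear kernel length (evens are rounded
#'   up to odd).
#' @param theta angle range in degrees, `[0, 180)`.
#' @param gamma range of the blend fraction between blurred and original.
#' @return A `motion_blur_params` list.
#' @export
motion_blur_params <- function(length = c(5L, 31L), theta = c(0, 180),
                               gamma = c(0.35, 0.8)) {
  if (any(length < 1)) .err("length must be >= 1", "canopyseg_param_error")
  structure(list(length = as.integer(length), theta = theta, gamma = gamma),
            class = "motion_blur_params")
}

#' Occlusion (cutout) parameters
#'
#' @param size edge length of the square patch in pixels.
#' @param fill constant grey level written into all channels of the patch.
#' @return An `occlusion_params` list.
#' @export
occlusion_params <- function(size = 50L, fill = 0) {
  if (size < 1) .err("size must be >= 1", "canopyseg_param_error")
  structure(list(size = as.integer(size), fill = fill),
            class = "occlusion_params")
}

# --- deterministic primitives ------------------------------------------------

#' Blend an image towards a fog colour through an opacity field
#'
#' The core fog transform: `I' = clip((1 - M) * I + C_fog * M, 0, 255)`
#' per pixel and channel, so each output value is a convex combination of
#' the input value and the fog colour.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param opacity `H x W` field in `[0, 1]`.
#' @param fog_color scalar grey level.
#' @return The blended image.
#' @export
fog_blend <- function(image, opacity, fog_color) {
  stopifnot(all(opacity >= 0), all(opacity <= 1))
  m <- array(opacity, dim(image))
  clip255((1 - m) * image + fog_color * m)
}

#' Additive brightness field (overexposure core)
#'
#' `I' = clip(I + beta * M, 0, 255)`: pixel-wise non-decreasing.
#'
#' @inheritParams fog_blend
#' @param beta maximum brightness increment.
#' @export
overexpose_blend <- function(image, opacity, beta) {
  clip255(image + beta * array(opacity, dim(image)))
}

#' Linear motion-blur point spread function
#'
#' An `L x L` kernel holding a centered horizontal line of ones, rotated by
#' `theta` degrees with bilinear interpolation and renormalized to unit sum.
#'
#' @param length odd kernel length in pixels (evens rounded up).
#' @param theta rotation angle in degrees.
#' @return `L x L` matrix summing to 1.
#' @export
motion_psf <- function(length, theta = 0) {
  if (length < 1) .err("psf length must be >= 1", "canopyseg_param_error")
  L <- as.integer(length)
  if (L %% 2 == 0) L <- L + 1L
  psf <- matrix(0, L, L)
  psf[(L + 1L) %/% 2L, ] <- 1
  if (theta %% 180 != 0) {
    # bilinear rotation about the center (inverse mapping, zero outside)
    th <- theta * pi / 180
    ctr <- (L + 1) / 2
    r <- matrix(seq_len(L) - ctr, L, L)
    c <- matrix(seq_len(L) - ctr, L, L, byrow = TRUE)
    sr <- cos(th) * r - sin(th) * c + ctr
    sc <- sin(th) * r + cos(th) * c + ctr
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    gv <- function(ri, ci) {
      v <- matrix(0, L, L)
      ok <- ri >= 1 & ri <= L & ci >= 1 & ci <= L
      v[ok] <- psf[cbind(ri[ok], ci[ok])]
      v
    }
    psf <- (1 - fr) * (1 - fc) * gv(r0, c0) + fr * (1 - fc) * gv(r0 + 1, c0) +
      (1 - fr) * fc * gv(r0, c0 + 1) + fr * fc * gv(r0 + 1, c0 + 1)
  }
  psf / sum(psf)
}

#' Apply a motion-blur kernel and blend with the original
#'
#' `B = conv(I, psf)` with reflect borders, then
#' `I' = clip((1 - gamma) * I + gamma * B, 0, 255)`.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param psf point spread function from [motion_psf()].
#' @param gamma blend fraction in `[0, 1]`.
#' @export
motion_blur_apply <- function(image, psf, gamma) {
  b <- .apply_planes(image, function(p) conv2_reflect(p, psf))
  clip255((1 - gamma) * image + gamma * b)
}

# Smooth opacity field from n circular spots: per-spot discs at their peak
# opacity combined by element-wise maximum (overlaps never exceed the peak
# range), then one Gaussian blur, then clipped to [0,1].
.spot_field <- function(H, W, centers, radius, peaks, kernel) {
  hh <- matrix(seq_len(H), H, W)
  ww <- matrix(seq_len(W), H, W, byrow = TRUE)
  M <- matrix(0, H, W)
  for (i in seq_len(nrow(centers))) {
    disc <- (hh - centers[i, 1])^2 + (ww - centers[i, 2])^2 <= radius^2
    M <- pmax(M, peaks[i] * disc)
  }
  clip01(gauss_smooth(M, kernel))
}

# --- randomized simulators ---------------------------------------------------

.runifr <- function(r) stats::runif(1, r[1], r[length(r)])

#' Draw one realization of the fog parameters
#'
#' The sampling step of [simulate_fog()], exposed so the realized values
#' (spot count, centers, peak opacities, fog colour, radius, kernel size)
#' can be inspected and audited against the configured ranges.
#'
#' @param params a [fog_params()] object.
#' @param H,W image size the draw is for.
#' @param seed integer seed (NULL = advance the session RNG).
#' @return List with `n`, `centers`, `peaks`, `fog_color`, `radius`,
#'   `kernel`.
#' @export
fog_draw <- function(params = fog_params(), H, W, seed = NULL) {
  with_seed(seed, {
    n <- sample(params$n_spots[1]:params$n_spots[2], 1L)
    radius <- params$radius_frac * min(H, W)
    list(n = n,
         centers = cbind(stats::runif(n, 1, H), stats::runif(n, 1, W)),
         peaks = stats::runif(n, params$alpha_peak[1], params$alpha_peak[2]),
         fog_color = .runifr(params$fog_color),
         radius = radius,
         kernel = odd_kernel(params$kernel_frac * radius))
  })
}

#' Simulate fog on an image
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param params a [fog_params()] object.
#' @param seed integer seed (NULL = advance the session RNG).
#' @return The degraded image; pixels where the opacity field is 0 are
#'   unchanged.
#' @export
simulate_fog <- function(image, params = fog_params(), seed = NULL) {
  d <- dim(image); H <- d[1]; W <- d[2]
  with_seed(seed, {
    dr <- fog_draw(params, H, W)
    M <- .spot_field(H, W, dr$centers, dr$radius, dr$peaks, dr$kernel)
    fog_blend(image, M, dr$fog_color)
  })
}

#' Draw one realization of the overexposure parameters
#'
#' @inheritParams fog_draw
#' @param params an [overexposure_params()] object.
#' @return List with `center`, `alpha`, `beta`, `radius`, `kernel`.
#' @export
overexposure_draw <- function(params = overexposure_params(), H, W,
                              seed = NULL) {
  with_seed(seed, {
    radius <- params$radius_frac * min(H, W)
    list(center = cbind(stats::runif(1, 1, H), stats::runif(1, 1, W)),
         alpha = .runifr(params$alpha),
         beta = .runifr(params$beta),
         radius = radius,
         kernel = odd_kernel(params$kernel_frac * radius))
  })
}

#' Simulate local overexposure on an image
#'
#' @inheritParams simulate_fog
#' @param params an [overexposure_params()] object.
#' @return The degraded image; every output pixel >= the input pixel.
#' @export
simulate_overexposure <- function(image, params = overexposure_params(),
                                  seed = NULL) {
  d <- dim(image); H <- d[1]; W <- d[2]
  with_seed(seed, {
    dr <- overexposure_draw(params, H, W)
    M <- .spot_field(H, W, dr$center, dr$radius, dr$alpha, dr$kernel)
    overexpose_blend(image, M, dr$beta)
  })
}

#' Draw one realization of the motion-blur parameters
#'
#' @inheritParams fog_draw
#' @param params a [motion_blur_params()] object.
#' @return List with `length` (odd), `theta`, `gamma`.
#' @export
motion_blur_draw <- function(params = motion_blur_params(), seed = NULL) {
  with_seed(seed, {
    L <- sample(params$length[1]:params$length[2], 1L)
    list(length = if (L %% 2 == 0) L + 1L else L,
         theta = stats::runif(1, params$theta[1], params$theta[2]),
         gamma = .runifr(params$gamma))
  })
}

#' Simulate directional motion blur on an image
#'
#' @inheritParams simulate_fog
#' @param params a [motion_blur_params()] object.
#' @export
simulate_motion_blur <- function(image, params = motion_blur_params(),
                                 seed = NULL) {
  with_seed(seed, {
    dr <- motion_blur_draw(params)
    motion_blur_apply(image, motion_psf(dr$length, dr$theta), dr$gamma)
  })
}

#' Simulate occlusion (cutout) on a sample
#'
#' Sets one `S x S` patch (uniformly placed, fully inside the frame) to the
#' fill value in all three channels. The mask is returned unchanged: the
#' model must infer the occluded canopy structure from the visible parts.
#'
#' @param sample a [new_sample()] object.
#' @param params an [occlusion_params()] object.
#' @param seed integer seed.
#' @return Sample with occluded image, identical mask, provenance
#'   `"esref_aug"`.
#' @export
simulate_occlusion <- function(sample, params = occlusion_params(),
                               seed = NULL) {
  d <- dim(sample$image); H <- d[1]; W <- d[2]; S <- params$size
  if (H < S || W < S)
    .err("image smaller than occlusion patch", "canopyseg_param_error")
  img <- with_seed(seed, {
    r0 <- sample.int(H - S + 1L, 1L)
    c0 <- sample.int(W - S + 1L, 1L)
    img <- sample$image
    img[r0:(r0 + S - 1L), c0:(c0 + S - 1L), ] <- params$fill
    img
  })
  new_sample(img, sample$mask, sample$id, "esref_aug")
}

#' Expand a training set with environment-simulation augmentations
#'
#' For each operation with multiplicity `m`, generates `m` degraded copies
#' of every input sample with freshly randomized parameters. When several
#' operations are requested within one copy they chain in the fixed order
#' fog, overexposure, motion blur, occlusion. Inputs must come from the
#' train side of a split (provenance `original` or `classic_aug`);
#' validation material raises a leakage error.
#'
#' @param train list of train-side [new_sample()] objects.
#' @param plan named list of per-operation multiplicities, e.g.
#'   `list(fog = 1, overexposure = 1, motion = 1, occlusion = 1)`.
#' @param seed integer seed.
#' @param fog,overexposure,motion,occlusion parameter objects for the four
#'   simulators.
#' @return `train` followed by the generated samples (provenance
#'   `"esref_aug"`); size `n * (1 + sum(multiplicities))`.
#' @export
expand_esref <- function(train,
                         plan = list(fog = 1L, overexposure = 1L,
                                     motion = 1L, occlusion = 1L),
                         seed = 11L,
                         fog = fog_params(),
                         overexposure = overexposure_params(),
                         motion = motion_blur_params(),
                         occlusion = occlusion_params()) {
  prov <- vapply(train, function(s) s$provenance, character(1))
  if (any(!prov %in% c("original", "classic_aug")))
    .err("expand_esref received already environment-augmented samples",
         "canopyseg_leakage_error")
  ops <- intersect(c("fog", "overexposure", "motion", "occlusion"),
                   names(plan))
  out <- with_seed(seed, {
    gen <- list()
    for (op in ops) {
      for (m in seq_len(plan[[op]])) {
        for (s in train) {
          a <- switch(op,
            fog = new_sample(simulate_fog(s$image, fog), s$mask, s$id,
                             "esref_aug"),
            overexposure = new_sample(simulate_overexposure(s$image,
                                                            overexposure),
                                      s$mask, s$id, "esref_aug"),
            motion = new_sample(simulate_motion_blur(s$image, motion),
                                s$mask, s$id, "esref_aug"),
            occlusion = simulate_occlusion(s, occlusion))
          a$id <- sprintf("%s_%s%02d", s$id, op, m)
          gen[[length(gen) + 1L]] <- a
        }
      }
    }
    gen
  })
  c(train, out)
}
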