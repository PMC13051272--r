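# Synthetic canopy-scene generator. Emulates the structural challenges of
# high-resolution UAV forest imagery -- irregular textured crown blobs,
# crown adhesion (overlapping crowns merge into one mask component) and a
# cluttered background -- without modelling real spectra. It exists so the
# full augmentation/training stack is testable without field data.

#' Parameters of the synthetic canopy-scene generator
#'
#' @param height,width scene size in pixels (>= 32).
#' @param n_crowns integer range `c(lo, hi)`: number of crowns drawn per
#'   scene (uniform). `c(0, 0)` renders pure background.
#' @param crown_radius pixel range for the nominal crown radius; each crown
#'   is a union of jittered discs around that radius, giving the lobed
#'   outline of a real deciduous crown.
#' @param crown_texture_scale spatial frequency of the multiplicative value
#'   noise that textures crowns and background (coarse-grid cells per scene
#'   edge; larger = finer texture).
#' @param background_clutter clutter intensity in `[0, 1]` scaling both the
#'   low-frequency background patchiness and the speckle noise.
#' @param fg_color_mean,bg_color_mean mean RGB triples in `[0, 255]` of
#'   crown and background; defaults emulate autumn broadleaf crowns over a
#'   mixed soil/understory background.
#' @param seed default integer seed carried with the parameters; the `seed`
#'   argument of [generate_scene()] overrides it.
#' @return A `scene_params` list.
#' @export
scene_params <- function(height = 256L, width = 256L,
                         n_crowns = c(3L, 6L),
                         crown_radius = c(20, 40),
                         crown_texture_scale = 8,
                         background_clutter = 0.3,
                         fg_color_mean = c(175, 110, 55),
                         bg_color_mean = c(85, 92, 70),
                         seed = 1L) {
  if (height < 32 || width < 32)
    .err("scene dimensions must be at least 32 pixels", "canopyseg_param_error")
  if (any(n_crowns < 0) || n_crowns[2] < n_crowns[1])
    .err("n_crowns must be a non-negative range", "canopyseg_param_error")
  if (any(crown_radius <= 0))
    .err("crown radii must be positive", "canopyseg_param_error")
  if (background_clutter < 0 || background_clutter > 1)
    .err("background_clutter must lie in [0,1]", "canopyseg_param_error")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_crowns = as.integer(n_crowns), crown_radius = crown_radius,
                 crown_texture_scale = crown_texture_scale,
                 background_clutter = background_clutter,
                 fg_color_mean = fg_color_mean, bg_color_mean = bg_color_mean,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# Low-frequency value noise: coarse random grid upsampled bilinearly.
.value_noise <- function(H, W, cells) {
  ch <- max(2L, as.integer(cells)); cw <- max(2L, as.integer(cells))
  resize_bilinear(matrix(stats::runif(ch * cw), ch, cw), H, W)
}

#' Generate one synthetic canopy scene
#'
#' Renders `n_crowns` lobed crown blobs (unions of jittered discs with
#' multiplicative value-noise texture) over a cluttered background, and
#' returns the paired binary mask in the field convention: canopy pixels
#' carry the value 1, everything else 0. Compositing happens in floating
#' point; 8-bit quantization (round half up) is applied last. The map
#' (params, seed) -> bytes is pure: identical seeds give identical scenes.
#'
#' @param params a [scene_params()] object.
#' @param seed integer seed; defaults to `params$seed`.
#' @return A [new_sample()] with provenance `"original"`.
#' @export
generate_scene <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "scene_params"))
  H <- params$height; W <- params$width
  with_seed(seed, {
    cl <- params$background_clutter
    tex <- .value_noise(H, W, params$crown_texture_scale)
    patch <- .value_noise(H, W, 4)
    img <- array(0, c(H, W, 3))
    for (c in 1:3) {
      bg <- params$bg_color_mean[c] * (1 + 0.6 * cl * (patch - 0.5)) +
        25 * cl * (tex - 0.5) +
        stats::rnorm(H * W, 0, 8 * cl)
      img[, , c] <- bg
    }
    mask <- matrix(0, H, W)
    n <- if (params$n_crowns[2] >= params$n_crowns[1])
      sample(params$n_crowns[1]:params$n_crowns[2], 1L) else params$n_crowns[1]
    if (n >= 1) {
      hh <- matrix(seq_len(H), H, W)
      ww <- matrix(seq_len(W), H, W, byrow = TRUE)
      ctex <- .value_noise(H, W, params$crown_texture_scale * 2)
      for (i in seq_len(n)) {
        r <- stats::runif(1, params$crown_radius[1], params$crown_radius[2])
        r <- min(r, (min(H, W) - 2) / 2)
        cy <- stats::runif(1, r + 1, H - r)
        cx <- stats::runif(1, r + 1, W - r)
        blob <- matrix(FALSE, H, W)
        for (j in 1:6) {  # lobed outline: jittered sub-discs
          oy <- stats::rnorm(1, 0, r / 3); ox <- stats::rnorm(1, 0, r / 3)
          rr <- r * stats::runif(1, 0.55, 0.95)
          y0 <- min(max(cy + oy, rr + 1), H - rr)
          x0 <- min(max(cx + ox, rr + 1), W - rr)
          blob <- blob | ((hh - y0)^2 + (ww - x0)^2 <= rr^2)
        }
        mask[blob] <- 1
        tint <- stats::rnorm(3, 0, 12)  # per-crown colour variation
        for (c in 1:3) {
          plane <- img[, , c]
          fg <- (params$fg_color_mean[c] + tint[c]) *
            (0.8 + 0.4 * ctex[blob]) + stats::rnorm(sum(blob), 0, 5)
          plane[blob] <- fg
          img[, , c] <- plane
        }
      }
    }
    img <- clip255(floor(img + 0.5))  # 8-bit quantization, half-up
    new_sample(img, mask, id = sprintf("scene_%010d", as.integer(seed) %% 1e9),
               provenance = "original")
  })
}

#' Generate a reproducible synthetic dataset
#'
#' Draws one independent sub-seed per scene from the master seed, so the
#' dataset is element-wise reproducible and its ordering stable.
#'
#' @param n number of scenes (>= 1).
#' @param params a [scene_params()] object.
#' @param seed master integer seed.
#' @return List of [new_sample()] objects, ids suffixed by index.
#' @export
generate_dataset <- function(n, params = scene_params(), seed = params$seed) {
  if (n < 1) .err("n must be >= 1", "canopyseg_param_error")
  sub <- with_seed(seed, sample.int(.Machine$integer.max, n))
  lapply(seq_len(n), function(i) {
    s <- generate_scene(params, seed = sub[i])
    s$id <- sprintf("scene_%03d", i)
    s
  })
}
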