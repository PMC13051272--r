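#' Paired image/mask sample
#'
#' The unit every augmentation and the training loop operate on: an 8-bit
#' RGB image (`H x W x 3` array, values in `[0, 255]`), a binary mask
#' (`H x W` matrix with 1 = canopy foreground, 0 = background), an
#' identifier and a provenance tag recording whether the sample is an
#' original or which augmentation family produced it.
#'
#' @param image `H x W x 3` numeric array in `[0, 255]`.
#' @param mask `H x W` matrix with values in `{0, 1}`.
#' @param id character identifier; pairs images and masks on disk.
#' @param provenance one of `"original"`, `"classic_aug"`, `"esref_aug"`.
#' @return An object of class `canopy_sample`.
#' @export
new_sample <- function(image, mask, id,
                       provenance = c("original", "classic_aug", "esref_aug")) {
  provenance <- match.arg(provenance)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    .err("image must be an H x W x 3 array", "canopyseg_format_error")
  if (is.null(dim(mask)) || !all(dim(mask) == dim(image)[1:2]))
    .err("mask must share H x W with the image", "canopyseg_format_error")
  if (!all(mask %in% c(0, 1)))
    .err("mask values must lie in {0,1}", "canopyseg_format_error")
  structure(list(image = image, mask = mask, id = as.character(id),
                 provenance = provenance),
            class = "canopy_sample")
}

#' @export
print.canopy_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<canopy_sample> %s [%dx%d, %s] fg=%.1f%%\n",
              x$id, d[1], d[2], x$provenance, 100 * mean(x$mask)))
  invisible(x)
}

#' Display a sample and its mask side by side
#'
#' @param x a [new_sample()] object.
#' @param ... ignored.
#' @export
plot.canopy_sample <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new(); graphics::plot.window(0:1, 0:1, asp = 1)
  graphics::rasterImage(x$image / 255, 0, 0, 1, 1)
  graphics::title(x$id)
  graphics::plot.new(); graphics::plot.window(0:1, 0:1, asp = 1)
  graphics::rasterImage(x$mask, 0, 0, 1, 1)
  graphics::title("mask")
  invisible(x)
}
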