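# Dataset input/output: paired PNG images and {0,1} masks, Labelme polygon
# rasterization, resizing and the leakage-safe train/validation split.
# Layout on disk: DIR/images/<id>.png and DIR/masks/<id>.png, paired by stem.
# Mask PNGs store the literal values {0,1} (8-bit); pass viz = TRUE to also
# emit a human-visible 0/255 rendering.

#' Write a dataset of samples to a directory
#'
#' @param samples list of [new_sample()] objects.
#' @param dir output directory; `images/` and `masks/` are created inside.
#' @param viz also write `masks_viz/` with foreground rendered as 255.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir, viz = FALSE) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (viz)
    dir.create(file.path(dir, "masks_viz"), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    png::writePNG(s$image / 255, file.path(dir, "images", paste0(s$id, ".png")))
    png::writePNG(s$mask / 255, file.path(dir, "masks", paste0(s$id, ".png")))
    if (viz)
      png::writePNG(s$mask, file.path(dir, "masks_viz", paste0(s$id, ".png")))
  }
  invisible(dir)
}

#' Read a dataset previously written by [write_dataset()]
#'
#' @param dir directory with `images/` and `masks/` subdirectories.
#' @param provenance provenance tag to assign to the loaded samples.
#' @return List of [new_sample()] objects in lexicographic id order.
#' @export
read_dataset <- function(dir, provenance = "original") {
  files <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$"))
  lapply(files, function(f) {
    id <- sub("\\.png$", "", f)
    img <- png::readPNG(file.path(dir, "images", f))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img <- round(img[, , 1:3, drop = FALSE] * 255)
    m <- png::readPNG(file.path(dir, "masks", f))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    new_sample(img, round(m * 255), id, provenance)
  })
}

# Even-odd point-in-polygon test for all pixel centers of an H x W grid.
# 0-based, row-major, pixel-center convention: pixel (r, c) sits at
# (x = c, y = r). Pixels whose center lies on a polygon edge are included.
.rasterize_polygon <- function(H, W, pts, eps = 1e-9) {
  x <- matrix(rep(0:(W - 1), each = H), H, W)
  y <- matrix(rep(0:(H - 1), W), H, W)
  n <- nrow(pts)
  inside <- matrix(FALSE, H, W)
  onedge <- matrix(FALSE, H, W)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- pts[i, 1]; y1 <- pts[i, 2]; x2 <- pts[j, 1]; y2 <- pts[j, 2]
    if (abs(y1 - y2) > 0) {
      cross <- ((y1 > y) != (y2 > y)) &
        (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
      inside <- xor(inside, cross)
    }
    # distance from pixel centers to the segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / len2)) else 0
    d2 <- (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
    onedge <- onedge | (d2 <= eps)
  }
  inside | onedge
}

#' Rasterize a Labelme annotation document into a sample
#'
#' Polygons whose label equals `target_label` are filled with 1; every
#' other area (including polygons of other labels) stays background, in
#' keeping with the binary canopy-vs-rest convention. The image is located
#' through the document's `imagePath` (relative to the JSON file) or
#' decoded from an embedded base64 `imageData` field.
#'
#' @param annotation path to a Labelme JSON file, or an equivalent parsed list.
#' @param target_label label of the foreground class.
#' @return A [new_sample()] with provenance `"original"`.
#' @export
load_labelme <- function(annotation, target_label) {
  base <- "."
  if (is.character(annotation)) {
    base <- dirname(annotation)
    annotation <- jsonlite::fromJSON(annotation, simplifyVector = FALSE)
  }
  H <- annotation$imageHeight; W <- annotation$imageWidth
  if (is.null(H) || is.null(W))
    .err("annotation lacks imageHeight/imageWidth", "canopyseg_format_error")
  img <- NULL
  if (!is.null(annotation$imageData) && nzchar(annotation$imageData)) {
    img <- png::readPNG(jsonlite::base64_dec(annotation$imageData))
  } else if (!is.null(annotation$imagePath)) {
    p <- file.path(base, annotation$imagePath)
    if (file.exists(p)) img <- png::readPNG(p)
  }
  if (is.null(img))
    .err("annotation references no readable image", "canopyseg_format_error")
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img <- round(img[, , 1:3, drop = FALSE] * 255)
  mask <- matrix(0, H, W)
  shapes <- annotation$shapes
  for (i in seq_along(shapes)) {
    sh <- shapes[[i]]
    if (!identical(sh$label, target_label)) next
    pts <- try(do.call(rbind, lapply(sh$points, function(p) as.numeric(p))),
               silent = TRUE)
    if (inherits(pts, "try-error") || is.null(pts) || ncol(pts) != 2 ||
        nrow(pts) < 3)
      .err(sprintf("malformed polygon in shape %d", i),
           "canopyseg_format_error")
    mask[.rasterize_polygon(H, W, pts)] <- 1
  }
  id <- sub("\\.[^.]*$", "", basename(annotation$imagePath %||% "labelme"))
  new_sample(img, mask, id, "original")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resize a sample to a square size
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbour interpolation and re-binarized, so mask values stay
#' in `{0, 1}`. Training pipelines use this to standardize inputs (the
#' reference configuration is 512 x 512).
#'
#' @param sample a [new_sample()] object.
#' @param size target edge length in pixels (>= 8).
#' @return The resized sample, provenance unchanged.
#' @export
resize_sample <- function(sample, size) {
  if (size < 8) .err("size must be >= 8", "canopyseg_param_error")
  size <- as.integer(size)
  d <- dim(sample$image)
  if (d[1] == size && d[2] == size) return(sample)
  img <- clip255(round(resize_bilinear(sample$image, size, size)))
  mask <- resize_nearest(sample$mask, size, size)
  mask <- (mask >= 0.5) * 1
  new_sample(img, mask, sample$id, sample$provenance)
}

#' Leakage-safe train/validation split
#'
#' Splits by id before any augmentation: the input must consist solely of
#' original samples (augmented provenance raises a leakage error), the
#' train side is then expanded by the augmentation pipelines, and the
#' validation side is never touched. `|train| = round(ratio * n)` with
#' round-half-away-from-zero.
#'
#' @param samples list of original [new_sample()] objects.
#' @param ratio train fraction, strictly between 0 and 1 (reference 0.8).
#' @param seed integer seed for the id permutation.
#' @return A `dataset_split` list with `train`, `val`, `ratio`, `seed`.
#' @export
split_dataset <- function(samples, ratio = 0.8, seed = 11L) {
  if (ratio <= 0 || ratio >= 1)
    .err("ratio must lie strictly between 0 and 1", "canopyseg_param_error")
  prov <- vapply(samples, function(s) s$provenance, character(1))
  if (any(prov != "original"))
    .err("augmented samples passed to split_dataset: augment after splitting",
         "canopyseg_leakage_error")
  n <- length(samples)
  n_train <- min(n, max(0L, round_half_away(ratio * n)))
  perm <- with_seed(seed, sample.int(n))
  structure(list(train = samples[perm[seq_len(n_train)]],
                 val = samples[perm[setdiff(seq_len(n), seq_len(n_train))]],
                 ratio = ratio, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d val (ratio %.2f, seed %d)\n",
              length(x$train), length(x$val), x$ratio, x$seed))
  invisible(x)
}

# Abort if any sample with augmented provenance sits in the validation set.
assert_no_leakage <- function(split) {
  prov <- vapply(split$val, function(s) s$provenance, character(1))
  if (any(prov != "original"))
    .err("augmented sample found in validation set", "canopyseg_leakage_error")
  invisible(TRUE)
}
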