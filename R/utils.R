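# Shared helpers: seeded evaluation, clipping, kernels, reflect-padded
# convolution. All randomized entry points funnel through with_seed() so the
# (input, params, seed) -> output map is a pure function.

.err <- function(msg, class) {
  stop(structure(class = c(class, "canopyseg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Evaluate expr under a temporary RNG state. seed = NULL uses (and advances)
# the session RNG, so callers can also manage reproducibility themselves.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Round half away from zero (commercial rounding), used for split sizes
# and 8-bit quantization.
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

# Nearest odd integer, floored at 3; "adaptive" kernel sizes go through this.
odd_kernel <- function(x) max(3L, 2L * as.integer(round((x - 1) / 2)) + 1L)

# Isotropic Gaussian kernel of odd size k, unit sum. Default sigma follows
# the usual size->sigma heuristic for smoothing kernels.
gaussian_kernel <- function(k, sigma = 0.3 * ((k - 1) * 0.5 - 1) + 0.8) {
  stopifnot(k %% 2 == 1)
  r <- (k - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}

.pad_reflect <- function(m, ph, pw = ph) {
  H <- nrow(m); W <- ncol(m)
  if (ph > H - 1 || pw > W - 1) stop("reflect padding wider than image")
  ri <- c((ph + 1):2, 1:H, (H - 1):(H - ph))[if (ph > 0) TRUE else -seq_len(0)]
  if (ph == 0) ri <- 1:H
  ci <- if (pw == 0) 1:W else c((pw + 1):2, 1:W, (W - 1):(W - pw))
  m[ri, ci, drop = FALSE]
}

# 2-D correlation with reflect border handling; kernel must be odd-sized.
conv2_reflect <- function(m, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  pm <- .pad_reflect(m, ph, pw)
  f <- EBImage::imageData(EBImage::filter2(pm, kern, boundary = "circular"))
  f[(ph + 1):(ph + nrow(m)), (pw + 1):(pw + ncol(m)), drop = FALSE]
}

# Gaussian smoothing of a 2-D field with an explicit odd kernel size,
# clamped (with a warning) when larger than the field.
gauss_smooth <- function(m, k) {
  kmax <- 2L * ((min(dim(m)) - 1L) %/% 2L) + 1L
  if (k > kmax) {
    warning("smoothing kernel larger than image; clamped to ", kmax)
    k <- kmax
  }
  conv2_reflect(m, gaussian_kernel(k))
}

# Bilinear resize of a 2-D plane or H x W x C array.
resize_bilinear <- function(a, H2, W2) {
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(a), w = H2, h = W2,
                                            filter = "bilinear"))
  dim(out) <- c(H2, W2, if (length(dim(a)) == 3) dim(a)[3] else NULL)
  if (length(dim(a)) == 2) dim(out) <- c(H2, W2)
  out
}

# Nearest-neighbour resize by explicit pixel-center index mapping.
resize_nearest <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(H, pmax(1L, floor((seq_len(H2) - 0.5) * H / H2) + 1L))
  ci <- pmin(W, pmax(1L, floor((seq_len(W2) - 0.5) * W / W2) + 1L))
  m[ri, ci, drop = FALSE]
}
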