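# Independent brute-force oracles: plain nested-loop R implementations of
# the tensor operators, sharing no code with the package's im2col/BLAS
# path. Used to pin down the block equations on small random tensors.

# Direct sliding-window convolution with explicit zero padding.
oracle_conv <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1,
                        groups = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  k <- dim(w)[1]; Cg <- dim(w)[3]; M <- dim(w)[4]
  Mg <- M / groups
  Ho <- (H + 2 * pad - dil * (k - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (k - 1) - 1) %/% stride + 1
  out <- array(0, c(Ho, Wo, M))
  for (m in seq_len(M)) {
    g <- ceiling(m / Mg)
    cin <- ((g - 1) * Cg + 1):(g * Cg)
    for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
      acc <- if (is.null(b)) 0 else b[m]
      for (cl in seq_len(Cg)) for (kw in seq_len(k)) for (kh in seq_len(k)) {
        h <- (ho - 1) * stride - pad + (kh - 1) * dil + 1
        ww <- (wo - 1) * stride - pad + (kw - 1) * dil + 1
        if (h >= 1 && h <= H && ww >= 1 && ww <= W)
          acc <- acc + w[kh, kw, cl, m] * x[h, ww, cin[cl]]
      }
      out[ho, wo, m] <- acc
    }
  }
  out
}

# Dense evaluation of the split-convolution equations: grouped 3x3 plus
# pointwise on the representative channels, pointwise on the redundant
# channels, pooled statistics, pairwise softmax fusion.
oracle_spconv <- function(x, cfg, w) {
  xr <- x[, , seq_len(cfg$rep), drop = FALSE]
  xd <- x[, , cfg$rep + seq_len(cfg$red), drop = FALSE]
  pad <- (cfg$kernel - 1) / 2
  u3 <- oracle_conv(xr, w$gwc, pad = pad, groups = cfg$groups) +
    oracle_conv(xr, w$pwc_rep)
  u1 <- oracle_conv(xd, w$pwc_red)
  s3 <- apply(u3, 3, mean)
  s1 <- apply(u1, 3, mean)
  beta <- exp(s3) / (exp(s3) + exp(s1))
  out <- array(0, dim(u3))
  for (c in seq_len(cfg$out_channels))
    out[, , c] <- beta[c] * u3[, , c] + (1 - beta[c]) * u1[, , c]
  out
}

# Position-by-position criss-cross attention: materializes the criss-cross
# context set per position as an explicit list (column first, then the row
# without the position itself), plain softmax, aggregation, residual add.
oracle_cca <- function(x, w) {
  H <- dim(x)[1]; W <- dim(x)[2]
  q <- oracle_conv(x, w$query)
  k <- oracle_conv(x, w$key)
  v <- oracle_conv(x, w$value)
  out <- array(0, dim(x))
  for (ww in seq_len(W)) for (h in seq_len(H)) {
    pos <- rbind(cbind(seq_len(H), ww),
                 cbind(h, setdiff(seq_len(W), ww)))
    d <- apply(pos, 1, function(p) sum(q[h, ww, ] * k[p[1], p[2], ]))
    a <- exp(d - max(d)); a <- a / sum(a)
    agg <- numeric(dim(x)[3])
    for (i in seq_len(nrow(pos)))
      agg <- agg + a[i] * v[pos[i, 1], pos[i, 2], ]
    out[h, ww, ] <- agg + x[h, ww, ]
  }
  out
}

# Context-guided downsampling, every stage spelled out.
oracle_cgb <- function(x, cfg, w, eps = 1e-5) {
  loc <- oracle_conv(x, w$floc, stride = 2, pad = 1)
  sur <- oracle_conv(x, w$fsur, stride = 2, pad = cfg$dilation,
                     dil = cfg$dilation)
  joi <- array(c(loc, sur), c(dim(loc)[1], dim(loc)[2], cfg$out_channels))
  for (c in seq_len(cfg$out_channels)) {
    z <- joi[, , c] / sqrt(1 + eps) * w$bn_gamma[c] + w$bn_beta[c]
    joi[, , c] <- ifelse(z < 0, w$prelu[c] * z, z)
  }
  g <- apply(joi, 3, mean)
  h1 <- pmax(0, drop(w$mlp_w1 %*% g) + w$mlp_b1)
  s <- 1 / (1 + exp(-(drop(w$mlp_w2 %*% h1) + w$mlp_b2)))
  for (c in seq_len(cfg$out_channels)) joi[, , c] <- joi[, , c] * s[c]
  joi
}

# Exact rational metric recomputation from raw masks (integer counts).
oracle_metrics <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  fp <- sum(pred == 1 & truth == 0); tn <- sum(pred == 0 & truth == 0)
  rat <- function(n, d) if (d == 0) 1 else n / d
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       miou = (rat(tp, tp + fp + fn) + rat(tn, tn + fn + fp)) / 2,
       pa = (tp + tn) / (tp + tn + fp + fn),
       mpa = (rat(tp, tp + fn) + rat(tn, tn + fp)) / 2,
       mprec = (rat(tp, tp + fp) + rat(tn, tn + fn)) / 2,
       mrec = (rat(tp, tp + fn) + rat(tn, tn + fp)) / 2)
}

# Small random feature map.
rand_fmap <- function(H, W, C) array(stats::rnorm(H * W * C), c(H, W, C))

# Small random RGB test image (8-bit integer grey levels) and sample.
rand_image <- function(H = 64, W = 64)
  array(floor(stats::runif(H * W * 3, 0, 256)), c(H, W, 3))

rand_mask <- function(H = 64, W = 64, p = 0.4)
  matrix(stats::rbinom(H * W, 1, p), H, W)

rand_sample <- function(H = 64, W = 64, id = "s", prov = "original") {
  new_sample(rand_image(H, W), rand_mask(H, W), id, prov)
}

# Desk-scale scene parameters used across the suite.
tiny_scene_params <- function(hw = 64)
  scene_params(height = hw, width = hw, n_crowns = c(2, 4),
               crown_radius = c(hw / 8, hw / 4))
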