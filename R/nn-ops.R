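# Differentiable tensor operators. Feature maps are H x W x C arrays
# (column-major, h fastest); this is the native R array layout, so no
# transposition happens between the augmentation code and the network.

.dim3 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("expected an H x W x C array")
  d
}

.conv_out <- function(H, k, stride, pad, dil) {
  (H + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
}

# 2-D convolution. w has dim (k, k, Cin/groups, Cout); optional bias
# is a length-Cout vector. Zero padding.
op_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L,
                      groups = 1L) {
  x <- ag_const(x); w <- ag_const(w)
  if (!is.null(b)) b <- ag_const(b)
  xv <- x$value; wv <- w$value
  d <- .dim3(xv); H <- d[1]; W <- d[2]; C <- d[3]
  k <- dim(wv)[1]; Cg <- dim(wv)[3]; M <- dim(wv)[4]
  if (C != Cg * groups) stop("conv2d: input channels do not match weights")
  if (M %% groups != 0L) stop("conv2d: output channels not divisible by groups")
  Mg <- M %/% groups
  Ho <- .conv_out(H, k, stride, pad, dil); Wo <- .conv_out(W, k, stride, pad, dil)

  if (k == 1L && stride == 1L && pad == 0L && dil == 1L && groups == 1L) {
    X2 <- matrix(xv, H * W, C)
    Wc <- matrix(wv, C, M)
    Y2 <- X2 %*% Wc
    if (!is.null(b)) Y2 <- sweep(Y2, 2L, b$value, "+")
    out <- array(Y2, c(H, W, M))
    parents <- list(x, w, if (is.null(b)) NULL else b)
    parents <- parents[!vapply(parents, is.null, logical(1))]
    return(ag_node(out, parents, function(g) {
      G2 <- matrix(g, H * W, M)
      dx <- array(G2 %*% t(Wc), c(H, W, C))
      dw <- array(t(X2) %*% G2, dim(wv))
      if (is.null(b)) list(dx, dw) else list(dx, dw, colSums(G2))
    }))
  }

  cols <- vector("list", groups)
  out <- array(0, c(Ho, Wo, M))
  for (g in seq_len(groups)) {
    ci <- ((g - 1L) * Cg + 1L):(g * Cg)
    oi <- ((g - 1L) * Mg + 1L):(g * Mg)
    xg <- xv[, , ci, drop = FALSE]
    cols[[g]] <- cpp_im2col(xg, H, W, Cg, k, stride, pad, dil)
    Wm <- matrix(wv[, , , oi, drop = FALSE], k * k * Cg, Mg)  # (k2Cg) x Mg
    Yg <- crossprod(Wm, cols[[g]])                            # Mg x (HoWo)
    out[, , oi] <- array(t(Yg), c(Ho, Wo, Mg))
  }
  if (!is.null(b)) out <- out + rep(b$value, each = Ho * Wo)
  parents <- list(x, w, if (is.null(b)) NULL else b)
  parents <- parents[!vapply(parents, is.null, logical(1))]
  ag_node(out, parents, function(gr) {
    dx <- array(0, c(H, W, C)); dw <- array(0, dim(wv))
    for (g in seq_len(groups)) {
      ci <- ((g - 1L) * Cg + 1L):(g * Cg)
      oi <- ((g - 1L) * Mg + 1L):(g * Mg)
      Gm <- t(matrix(gr[, , oi, drop = FALSE], Ho * Wo, Mg))  # Mg x HoWo
      dw[, , , oi] <- array(tcrossprod(cols[[g]], Gm), c(k, k, Cg, Mg))
      Wm <- matrix(wv[, , , oi, drop = FALSE], k * k * Cg, Mg)
      dcols <- Wm %*% Gm
      dx[, , ci] <- cpp_col2im(dcols, H, W, Cg, k, stride, pad, dil)
    }
    if (is.null(b)) list(dx, dw)
    else list(dx, dw, colSums(matrix(gr, Ho * Wo, M)))
  })
}

op_relu <- function(x) {
  x <- ag_const(x)
  mask <- x$value > 0
  ag_node(x$value * mask, list(x), function(g) list(g * mask))
}

# Parametric ReLU with one learnable slope per channel.
op_prelu <- function(x, alpha) {
  x <- ag_const(x); alpha <- ag_const(alpha)
  d <- .dim3(x$value)
  neg <- x$value < 0
  a <- rep(alpha$value, each = d[1] * d[2])
  out <- ifelse(neg, a * x$value, x$value)
  ag_node(out, list(x, alpha), function(g) {
    dx <- ifelse(neg, a * g, g)
    da <- colSums(matrix(g * x$value * neg, d[1] * d[2], d[3]))
    list(dx, da)
  })
}

op_maxpool2 <- function(x) {
  x <- ag_const(x)
  d <- .dim3(x$value)
  r <- cpp_maxpool2_fwd(x$value, d[1], d[2], d[3])
  idx <- r$idx + 1L
  ag_node(r$out, list(x), function(g)
    list(cpp_maxpool2_bwd(g, idx - 1L, d[1], d[2], d[3])))
}

op_upsample2 <- function(x) {
  x <- ag_const(x)
  d <- .dim3(x$value)
  out <- cpp_upsample2_fwd(x$value, d[1], d[2], d[3])
  ag_node(out, list(x), function(g)
    list(cpp_upsample2_bwd(g, d[1], d[2], d[3])))
}

op_concat <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  da <- .dim3(a$value); db <- .dim3(b$value)
  stopifnot(da[1] == db[1], da[2] == db[2])
  out <- array(c(a$value, b$value), c(da[1], da[2], da[3] + db[3]))
  ag_node(out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

op_slice <- function(x, channels) {
  x <- ag_const(x)
  d <- .dim3(x$value)
  out <- x$value[, , channels, drop = FALSE]
  ag_node(out, list(x), function(g) {
    dx <- array(0, d)
    dx[, , channels] <- g
    list(dx)
  })
}

op_add <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

op_sub <- function(a, b) {
  a <- ag_const(a); b <- ag_const(b)
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

op_scale <- function(x, s) {
  x <- ag_const(x)
  ag_node(x$value * s, list(x), function(g) list(g * s))
}

# Channel-wise scaling: s is a length-C vector (node), broadcast over H x W.
op_scale_channels <- function(x, s) {
  x <- ag_const(x); s <- ag_const(s)
  d <- .dim3(x$value)
  sv <- rep(s$value, each = d[1] * d[2])
  ag_node(x$value * sv, list(x, s), function(g) {
    ds <- colSums(matrix(g * x$value, d[1] * d[2], d[3]))
    list(g * sv, ds)
  })
}

# Fixed-statistics batch normalization: running mean/var are constants,
# gamma/beta learnable. Deterministic and batch-size independent.
op_bn_fixed <- function(x, gamma, beta, mean = NULL, var = NULL, eps = 1e-5) {
  x <- ag_const(x); gamma <- ag_const(gamma); beta <- ag_const(beta)
  d <- .dim3(x$value)
  C <- d[3]
  if (is.null(mean)) mean <- numeric(C)
  if (is.null(var)) var <- rep(1, C)
  inv <- 1 / sqrt(var + eps)
  xh <- (x$value - rep(mean, each = d[1] * d[2])) * rep(inv, each = d[1] * d[2])
  gv <- rep(gamma$value, each = d[1] * d[2])
  out <- gv * xh + rep(beta$value, each = d[1] * d[2])
  ag_node(out, list(x, gamma, beta), function(g) {
    list(g * gv * rep(inv, each = d[1] * d[2]),
         colSums(matrix(g * xh, d[1] * d[2], C)),
         colSums(matrix(g, d[1] * d[2], C)))
  })
}

op_gap <- function(x) {
  x <- ag_const(x)
  d <- .dim3(x$value)
  out <- colMeans(matrix(x$value, d[1] * d[2], d[3]))
  ag_node(out, list(x), function(g)
    list(array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d)))
}

# Dense layer on a vector: W is (out x in).
op_dense <- function(v, w, b = NULL) {
  v <- ag_const(v); w <- ag_const(w)
  if (!is.null(b)) b <- ag_const(b)
  out <- drop(w$value %*% v$value)
  if (!is.null(b)) out <- out + b$value
  parents <- list(v, w, if (is.null(b)) NULL else b)
  parents <- parents[!vapply(parents, is.null, logical(1))]
  ag_node(out, parents, function(g) {
    dv <- drop(crossprod(w$value, g))
    dw <- outer(g, v$value)
    if (is.null(b)) list(dv, dw) else list(dv, dw, g)
  })
}

op_sigmoid <- function(x) {
  x <- ag_const(x)
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

op_relu_vec <- function(x) {
  x <- ag_const(x)
  mask <- x$value > 0
  ag_node(x$value * mask, list(x), function(g) list(g * mask))
}

# Criss-cross attention core: affinity + softmax + aggregation (no residual).
op_cca_aggregate <- function(q, k, v) {
  q <- ag_const(q); k <- ag_const(k); v <- ag_const(v)
  dq <- .dim3(q$value); dv <- .dim3(v$value)
  H <- dq[1]; W <- dq[2]; Cp <- dq[3]; C <- dv[3]
  r <- cpp_cca_fwd(q$value, k$value, v$value, H, W, Cp, C)
  node <- ag_node(r$out, list(q, k, v), function(g) {
    b <- cpp_cca_bwd(q$value, k$value, v$value, r$attn, g, H, W, Cp, C)
    list(b$dq, b$dk, b$dv)
  })
  attr(node$value, "attention") <- NULL  # attention map exposed separately
  node$attn <- r$attn
  node
}

# Mean per-pixel softmax cross-entropy against a {0,1} mask.
op_softmax_ce <- function(logits, mask) {
  logits <- ag_const(logits)
  d <- .dim3(logits$value)
  if (d[3] != 2L) stop("expected 2-channel logits")
  if (!all(dim(mask) == d[1:2])) stop("mask/logit shape mismatch")
  if (!all(mask %in% c(0, 1))) stop("mask values must lie in {0,1}")
  l0 <- logits$value[, , 1]; l1 <- logits$value[, , 2]
  m <- pmax(l0, l1)
  lse <- m + log(exp(l0 - m) + exp(l1 - m))
  ltrue <- ifelse(mask == 1, l1, l0)
  n <- d[1] * d[2]
  loss <- sum(lse - ltrue) / n
  ag_node(loss, list(logits), function(g) {
    p1 <- exp(l1 - lse)
    dl <- array(0, d)
    dl[, , 1] <- ((1 - p1) - (1 - mask)) * g / n
    dl[, , 2] <- (p1 - mask) * g / n
    list(dl)
  })
}
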