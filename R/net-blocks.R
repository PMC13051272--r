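# The three encoder operators. Each is a pure tensor operator usable
# outside the full model: configs + explicitly passed weights, plain
# H x W x C arrays in and out (autodiff nodes pass through transparently,
# which is how the model assembly trains them).

.as_node_in <- function(x) {
  if (ag_is_node(x)) list(x = x, raw = FALSE)
  else list(x = ag_const(x), raw = TRUE)
}

.kaiming <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

# --- SPConv ------------------------------------------------------------------

#' Split-based convolution configuration
#'
#' Input channels are partitioned at `split_ratio` into a representative
#' part (3x3 grouped convolution plus a parallel 1x1 convolution, summed)
#' and a redundant part (1x1 convolution only); the two branch outputs are
#' fused by parameter-free channel-wise soft attention over their global
#' average pooled statistics. Spatial resolution is strictly preserved.
#'
#' @param in_channels,out_channels channel counts `L`, `M`.
#' @param kernel representative-branch kernel size (3).
#' @param split_ratio fraction of channels sent to the representative
#'   branch, in (0, 1).
#' @param groups group count of the grouped convolution (2).
#' @return An `spconv_config` list with resolved `rep`/`red` channel counts.
#' @export
spconv_config <- function(in_channels, out_channels, kernel = 3L,
                          split_ratio = 0.5, groups = 2L) {
  rep <- as.integer(round(split_ratio * in_channels))
  red <- as.integer(in_channels) - rep
  if (rep < 1 || red < 1)
    .err("split_ratio leaves an empty branch", "canopyseg_config_error")
  if (rep %% groups != 0)
    .err("representative channels not divisible by groups",
         "canopyseg_config_error")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), split_ratio = split_ratio,
                 groups = as.integer(groups), rep = rep, red = red),
            class = "spconv_config")
}

#' Initialize SPConv weights
#'
#' @param cfg an [spconv_config()].
#' @param seed integer seed for the Kaiming-style draws.
#' @return List with `gwc` (k x k x rep/G x M), `pwc_rep` (1 x 1 x rep x M)
#'   and `pwc_red` (1 x 1 x red x M) kernels; all convolutions bias-free.
#' @export
spconv_init <- function(cfg, seed = NULL) {
  k <- cfg$kernel; G <- cfg$groups
  with_seed(seed, list(
    gwc = .kaiming(c(k, k, cfg$rep %/% G, cfg$out_channels),
                   k * k * cfg$rep / G),
    pwc_rep = .kaiming(c(1L, 1L, cfg$rep, cfg$out_channels), cfg$rep),
    pwc_red = .kaiming(c(1L, 1L, cfg$red, cfg$out_channels), cfg$red)))
}

#' SPConv forward pass
#'
#' Representative branch `U3 = GWC(x_rep) + PWC(x_rep)`, redundant branch
#' `U1 = PWC(x_red)`; channel statistics `S3 = GAP(U3)`, `S1 = GAP(U1)`;
#' fusion weights `beta = exp(S3) / (exp(S3) + exp(S1))`, `gamma = 1 - beta`
#' per channel; output `Y = beta * U3 + gamma * U1`. `H x W` is unchanged.
#'
#' @param x `H x W x L` array (or autodiff node).
#' @param cfg an [spconv_config()].
#' @param w weights from [spconv_init()].
#' @return `H x W x M` array with attribute `fusion_beta` (the per-channel
#'   weights), or a node when `x` is a node.
#' @export
spconv_forward <- function(x, cfg, w) {
  xi <- .as_node_in(x)
  d <- .dim3(ag_value(xi$x))
  if (d[3] != cfg$in_channels)
    .err("input channels do not match spconv_config", "canopyseg_config_error")
  pad <- (cfg$kernel - 1L) %/% 2L
  x_rep <- op_slice(xi$x, seq_len(cfg$rep))
  x_red <- op_slice(xi$x, cfg$rep + seq_len(cfg$red))
  u3 <- op_add(op_conv2d(x_rep, w$gwc, pad = pad, groups = cfg$groups),
               op_conv2d(x_rep, w$pwc_rep))
  u1 <- op_conv2d(x_red, w$pwc_red)
  beta <- op_sigmoid(op_sub(op_gap(u3), op_gap(u1)))  # softmax over 2 stats
  gamma <- op_sub(ag_const(rep(1, cfg$out_channels)), beta)
  y <- op_add(op_scale_channels(u3, beta), op_scale_channels(u1, gamma))
  if (xi$raw) {
    out <- y$value
    attr(out, "fusion_beta") <- beta$value
    out
  } else y
}

#' SPConv parameter count
#'
#' Bias-free total over the three kernels:
#' `(rep/G) * M * k^2  +  rep * M  +  red * M`, always below the vanilla
#' `L * M * k^2` for `k = 3`, `G = 2`.
#'
#' @param cfg an [spconv_config()].
#' @return Integer parameter count.
#' @export
spconv_param_count <- function(cfg) {
  as.integer((cfg$rep %/% cfg$groups) * cfg$out_channels * cfg$kernel^2 +
               cfg$rep * cfg$out_channels + cfg$red * cfg$out_channels)
}

# --- Criss-cross attention ---------------------------------------------------

#' Initialize criss-cross attention weights
#'
#' Query/key 1x1 projections to `proj_channels` (`C' < C`; default `C / 8`)
#' and a value 1x1 projection back to `C`. All bias-free.
#'
#' @param channels input/output channel count `C`.
#' @param proj_channels reduced channel count `C'`.
#' @param seed integer seed.
#' @return List with `query`, `key`, `value` kernels and the channel counts.
#' @export
cca_init <- function(channels, proj_channels = max(1L, channels %/% 8L),
                     seed = NULL) {
  if (proj_channels >= channels)
    .err("proj_channels must be smaller than channels",
         "canopyseg_config_error")
  with_seed(seed, list(
    query = .kaiming(c(1L, 1L, channels, proj_channels), channels),
    key = .kaiming(c(1L, 1L, channels, proj_channels), channels),
    value = .kaiming(c(1L, 1L, channels, channels), channels),
    channels = as.integer(channels),
    proj_channels = as.integer(proj_channels)))
}

#' Criss-cross attention forward pass
#'
#' For each position `u`, affinities `d[i, u] = Q_u . K[i, u]` are taken
#' over the `H + W - 1` positions sharing u's row or column (the position
#' itself counted once, in the column pass), softmax-normalized into the
#' attention map `A` of shape `(H + W - 1) x H x W`, and used to aggregate
#' the value projection; the input is added back residually, so channel
#' depth and spatial resolution are strictly unchanged.
#'
#' @param x `H x W x C` array (or autodiff node).
#' @param w weights from [cca_init()].
#' @return `H x W x C` array with attribute `attention` (the normalized
#'   attention map), or a node when `x` is a node.
#' @export
cca_forward <- function(x, w) {
  xi <- .as_node_in(x)
  d <- .dim3(ag_value(xi$x))
  if (d[3] != w$channels)
    .err("input channels do not match cca weights", "canopyseg_config_error")
  q <- op_conv2d(xi$x, w$query)
  k <- op_conv2d(xi$x, w$key)
  v <- op_conv2d(xi$x, w$value)
  agg <- op_cca_aggregate(q, k, v)
  out <- op_add(agg, xi$x)
  if (xi$raw) {
    y <- out$value
    attr(y, "attention") <- agg$attn
    y
  } else out
}

# --- Context-guided downsampling ---------------------------------------------

#' Context-guided downsampling configuration
#'
#' @param in_channels,out_channels channel counts; `out_channels` must be
#'   even (the local and surrounding extractors each emit half).
#' @param dilation dilation of the surrounding-context extractor (2).
#' @param mlp_reduction reduction factor of the global-context perceptron
#'   hidden width (`out_channels / mlp_reduction`, floored at 1).
#' @return A `cgb_config` list.
#' @export
cgb_config <- function(in_channels, out_channels, dilation = 2L,
                       mlp_reduction = 16L) {
  if (out_channels %% 2 != 0)
    .err("out_channels must be even", "canopyseg_config_error")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 dilation = as.integer(dilation),
                 mlp_reduction = as.integer(mlp_reduction),
                 hidden = max(1L, as.integer(out_channels) %/%
                                as.integer(mlp_reduction))),
            class = "cgb_config")
}

#' Initialize context-guided downsampling weights
#'
#' @param cfg a [cgb_config()].
#' @param seed integer seed.
#' @return List with the local (`floc`) and surrounding (`fsur`) stride-2
#'   kernels, batch-norm affine (`bn_gamma`, `bn_beta`), PReLU slopes
#'   (`prelu`) and the two perceptron layers (`mlp_w1/b1/w2/b2`).
#' @export
cgb_init <- function(cfg, seed = NULL) {
  half <- cfg$out_channels %/% 2L
  with_seed(seed, list(
    floc = .kaiming(c(3L, 3L, cfg$in_channels, half), 9 * cfg$in_channels),
    fsur = .kaiming(c(3L, 3L, cfg$in_channels, half), 9 * cfg$in_channels),
    bn_gamma = rep(1, cfg$out_channels),
    bn_beta = rep(0, cfg$out_channels),
    prelu = rep(0.25, cfg$out_channels),
    mlp_w1 = .kaiming(c(cfg$hidden, cfg$out_channels), cfg$out_channels),
    mlp_b1 = rep(0, cfg$hidden),
    mlp_w2 = .kaiming(c(cfg$out_channels, cfg$hidden), cfg$hidden),
    mlp_b2 = rep(0, cfg$out_channels)))
}

#' Context-guided downsampling forward pass
#'
#' Local extractor: 3x3 stride-2 convolution to `out_channels / 2`;
#' surrounding-context extractor: 3x3 stride-2 dilated convolution to
#' `out_channels / 2`; joint feature: concatenation + batch normalization
#' (fixed statistics) + parametric ReLU; global context: global average
#' pooling + two-layer perceptron with sigmoid-bounded per-channel weights
#' applied by channel-wise scaling. Output is `out_channels x H/2 x W/2`.
#'
#' @param x `H x W x C_in` array with even `H`, `W` (or autodiff node).
#' @param cfg a [cgb_config()].
#' @param w weights from [cgb_init()].
#' @param glo apply the global-context reweighting (disable to inspect the
#'   unscaled joint feature).
#' @return `H/2 x W/2 x C_out` array, or a node when `x` is a node.
#' @export
cgb_down_forward <- function(x, cfg, w, glo = TRUE) {
  xi <- .as_node_in(x)
  d <- .dim3(ag_value(xi$x))
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0)
    .err("context-guided downsampling requires even H and W",
         "canopyseg_contract_error")
  if (d[3] != cfg$in_channels)
    .err("input channels do not match cgb_config", "canopyseg_config_error")
  loc <- op_conv2d(xi$x, w$floc, stride = 2L, pad = 1L)
  sur <- op_conv2d(xi$x, w$fsur, stride = 2L, pad = cfg$dilation,
                   dil = cfg$dilation)
  joi <- op_prelu(op_bn_fixed(op_concat(loc, sur), w$bn_gamma, w$bn_beta),
                  w$prelu)
  out <- joi
  if (glo) {
    s <- op_sigmoid(op_dense(op_relu_vec(op_dense(op_gap(joi), w$mlp_w1,
                                                  w$mlp_b1)),
                             w$mlp_w2, w$mlp_b2))
    out <- op_scale_channels(joi, s)
  }
  if (xi$raw) out$value else out
}

#' Context-guided downsampling parameter count
#'
#' @param cfg a [cgb_config()].
#' @return Integer count over both extractors, the batch-norm affine, the
#'   PReLU slopes and the perceptron.
#' @export
cgb_param_count <- function(cfg) {
  half <- cfg$out_channels %/% 2L
  2L * 9L * cfg$in_channels * half +         # floc + fsur
    2L * cfg$out_channels +                  # bn affine
    cfg$out_channels +                       # prelu slopes
    cfg$hidden * cfg$out_channels + cfg$hidden +
    cfg$out_channels * cfg$hidden + cfg$out_channels
}
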