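# U-Net with a VGG16 convolutional backbone, plus the attention
# context-guided variant: split-based convolutions replace every encoder
# 3x3 convolution except the stem, criss-cross attention sits after the
# deepest encoder stage, and context-guided downsampling replaces the four
# max-pools. The decoder (bilinear x2 upsampling, skip concatenation, two
# 3x3 convolutions per stage, 1x1 head) is identical in all variants.

#' Model specification
#'
#' The three toggles are independent; all off is the baseline U-Net, all
#' on is the full attention context-guided network. `width` scales every
#' channel count (value 1 is the reference VGG16 layout; small fractions
#' give desk-scale models for CPU experiments).
#'
#' @param use_spconv replace non-stem encoder convolutions with
#'   split-based convolutions.
#' @param use_cca insert criss-cross attention after the deepest encoder
#'   stage.
#' @param use_cgb_down replace max-pools with context-guided downsampling
#'   (output channels equal the next stage's width).
#' @param num_classes output classes (2: background, canopy).
#' @param input_size reference square input edge; forward accepts any size
#'   divisible by 16.
#' @param width channel multiplier; widths are kept divisible by 4 so the
#'   split/grouped convolutions stay well-formed.
#' @param seed integer seed for deterministic weight initialization.
#' @return A `model_spec` list with resolved encoder/decoder channels.
#' @export
model_spec <- function(use_spconv = FALSE, use_cca = FALSE,
                       use_cgb_down = FALSE, num_classes = 2L,
                       input_size = 512L, width = 1, seed = 11L) {
  scale <- function(ch) pmax(4L, as.integer(4L * round(ch * width / 4)))
  structure(list(
    use_spconv = use_spconv, use_cca = use_cca, use_cgb_down = use_cgb_down,
    num_classes = as.integer(num_classes), input_size = as.integer(input_size),
    width = width,
    encoder_channels = lapply(list(c(64L, 64L), c(128L, 128L),
                                   c(256L, 256L, 256L), c(512L, 512L, 512L),
                                   c(512L, 512L, 512L)), scale),
    decoder_channels = scale(c(512L, 256L, 128L, 64L)),
    seed = as.integer(seed)),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> spconv=%s cca=%s cgb_down=%s width=%g seed=%d\n",
              x$use_spconv, x$use_cca, x$use_cgb_down, x$width, x$seed))
  invisible(x)
}

.conv_init <- function(k, cin, cout) {
  list(w = .kaiming(c(k, k, cin, cout), k * k * cin), b = rep(0, cout))
}

#' Build a segmentation model from a specification
#'
#' Weights are drawn deterministically from `spec$seed` (Kaiming-style,
#' no pretraining), wrapped as autodiff leaves so the same object serves
#' inference and training.
#'
#' @param spec a [model_spec()].
#' @return A `canopyseg_model`: the spec, a layer plan and a named list of
#'   parameter leaves.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  enc <- spec$encoder_channels
  dec <- spec$decoder_channels
  params <- list()
  plan <- list(encoder = list(), down = list(), cca = NULL,
               decoder = list(), head = NULL)
  with_seed(spec$seed, {
    in_ch <- 3L
    for (s in seq_along(enc)) {
      stage <- list()
      for (j in seq_along(enc[[s]])) {
        out_ch <- enc[[s]][j]
        nm <- sprintf("enc_s%d_c%d", s, j)
        stem <- (s == 1L && j == 1L)
        if (spec$use_spconv && !stem) {
          cfg <- spconv_config(in_ch, out_ch)
          w <- spconv_init(cfg)
          params[[paste0(nm, "_gwc")]] <- w$gwc
          params[[paste0(nm, "_pwc_rep")]] <- w$pwc_rep
          params[[paste0(nm, "_pwc_red")]] <- w$pwc_red
          stage[[j]] <- list(type = "spconv", cfg = cfg, name = nm)
        } else {
          w <- .conv_init(3L, in_ch, out_ch)
          params[[paste0(nm, "_w")]] <- w$w
          params[[paste0(nm, "_b")]] <- w$b
          stage[[j]] <- list(type = "conv", name = nm)
        }
        in_ch <- out_ch
      }
      plan$encoder[[s]] <- stage
      if (s < length(enc)) {
        if (spec$use_cgb_down) {
          cfg <- cgb_config(in_ch, enc[[s + 1L]][1])
          w <- cgb_init(cfg)
          nm <- sprintf("down%d", s)
          for (f in names(w)) params[[paste0(nm, "_", f)]] <- w[[f]]
          plan$down[[s]] <- list(type = "cgb", cfg = cfg, name = nm)
          in_ch <- cfg$out_channels
        } else {
          plan$down[[s]] <- list(type = "maxpool")
        }
      }
    }
    if (spec$use_cca) {
      w <- cca_init(in_ch)
      params$cca_query <- w$query
      params$cca_key <- w$key
      params$cca_value <- w$value
      plan$cca <- list(channels = w$channels,
                       proj_channels = w$proj_channels)
    }
    skip_ch <- vapply(enc[1:4], function(v) v[length(v)], integer(1))
    for (i in seq_along(dec)) {
      skip <- skip_ch[5L - i]
      nm1 <- sprintf("dec%d_c1", i); nm2 <- sprintf("dec%d_c2", i)
      w1 <- .conv_init(3L, in_ch + skip, dec[i])
      w2 <- .conv_init(3L, dec[i], dec[i])
      params[[paste0(nm1, "_w")]] <- w1$w; params[[paste0(nm1, "_b")]] <- w1$b
      params[[paste0(nm2, "_w")]] <- w2$w; params[[paste0(nm2, "_b")]] <- w2$b
      plan$decoder[[i]] <- list(names = c(nm1, nm2))
      in_ch <- dec[i]
    }
    wh <- .conv_init(1L, in_ch, spec$num_classes)
    params$head_w <- wh$w; params$head_b <- wh$b
    plan$head <- "head"
  })
  structure(list(spec = spec, plan = plan,
                 params = lapply(params, ag_param)),
            class = "canopyseg_model")
}

#' @export
print.canopyseg_model <- function(x, ...) {
  r <- param_report(x)
  cat(sprintf("<canopyseg_model> spconv=%s cca=%s cgb_down=%s | %s params, %.2f MB\n",
              x$spec$use_spconv, x$spec$use_cca, x$spec$use_cgb_down,
              format(r$total_params, big.mark = ","), r$size_mb))
  invisible(x)
}

# Graph-building forward over autodiff nodes. x: H x W x 3 node/array with
# values already scaled to [0, 1].
.forward_nodes <- function(model, x) {
  p <- model$params
  plan <- model$plan
  spconv_w <- function(nm) list(gwc = p[[paste0(nm, "_gwc")]],
                                pwc_rep = p[[paste0(nm, "_pwc_rep")]],
                                pwc_red = p[[paste0(nm, "_pwc_red")]])
  cgb_w <- function(nm) {
    fields <- c("floc", "fsur", "bn_gamma", "bn_beta", "prelu",
                "mlp_w1", "mlp_b1", "mlp_w2", "mlp_b2")
    stats::setNames(lapply(fields, function(f) p[[paste0(nm, "_", f)]]), fields)
  }
  skips <- list()
  for (s in seq_along(plan$encoder)) {
    for (layer in plan$encoder[[s]]) {
      x <- if (layer$type == "spconv")
        spconv_forward(x, layer$cfg, spconv_w(layer$name))
      else op_conv2d(x, p[[paste0(layer$name, "_w")]],
                     p[[paste0(layer$name, "_b")]], pad = 1L)
      x <- op_relu(x)
    }
    if (s < length(plan$encoder)) {
      skips[[s]] <- x
      dn <- plan$down[[s]]
      x <- if (dn$type == "cgb") cgb_down_forward(x, dn$cfg, cgb_w(dn$name))
      else op_maxpool2(x)
    }
  }
  if (!is.null(plan$cca))
    x <- cca_forward(x, list(query = p$cca_query, key = p$cca_key,
                             value = p$cca_value,
                             channels = plan$cca$channels,
                             proj_channels = plan$cca$proj_channels))
  for (i in seq_along(plan$decoder)) {
    x <- op_concat(op_upsample2(x), skips[[5L - i]])
    for (nm in plan$decoder[[i]]$names) {
      x <- op_relu(op_conv2d(x, p[[paste0(nm, "_w")]],
                             p[[paste0(nm, "_b")]], pad = 1L))
    }
  }
  op_conv2d(x, p$head_w, p$head_b)
}

#' Forward pass: image to per-pixel class logits
#'
#' @param model a [build_model()] object.
#' @param image `H x W x 3` array in `[0, 255]`; `H`, `W` divisible by 16.
#' @return `H x W x num_classes` logit array (channel 1 = background,
#'   channel 2 = canopy).
#' @export
model_forward <- function(model, image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L || d[1] %% 16 != 0 || d[2] %% 16 != 0)
    .err("input must be H x W x 3 with H, W divisible by 16",
         "canopyseg_config_error")
  ag_reset()
  on.exit(ag_reset())
  .forward_nodes(model, image / 255)$value
}

#' Predict a binary canopy mask
#'
#' @inheritParams model_forward
#' @return `H x W` matrix in `{0, 1}` (per-pixel argmax of the logits).
#' @export
predict_mask <- function(model, image) {
  l <- model_forward(model, image)
  (l[, , 2] > l[, , 1]) * 1
}

#' Parameter accounting of a model
#'
#' Counts every trainable parameter and converts to megabytes assuming
#' 32-bit storage (`4 * P / 2^20`), with a per-component breakdown.
#'
#' @param model a [build_model()] object.
#' @return A `param_report` list: `total_params`, `size_mb`, `per_block`.
#' @export
param_report <- function(model) {
  counts <- vapply(model$params, function(p) length(p$value), numeric(1))
  comp <- sub("^(enc|down|cca|dec|head).*", "\\1", names(counts))
  comp[comp == "enc"] <- "encoder"
  comp[comp == "down"] <- "downsample"
  comp[comp == "cca"] <- "attention"
  comp[comp == "dec"] <- "decoder"
  per_block <- tapply(counts, comp, sum)
  total <- sum(counts)
  structure(list(total_params = total, size_mb = 4 * total / 2^20,
                 per_block = per_block),
            class = "param_report")
}

#' @export
print.param_report <- function(x, ...) {
  cat(sprintf("<param_report> %s params = %.2f MB\n",
              format(x$total_params, big.mark = ","), x$size_mb))
  for (nm in names(x$per_block))
    cat(sprintf("  %-10s %s\n", nm, format(x$per_block[[nm]], big.mark = ",")))
  invisible(x)
}

#' The eight-variant ablation grid
#'
#' Full toggle lattice over the three modules in the standard order:
#' row 1 is the baseline (no modules), rows 2-4 single modules, rows 5-7
#' pairs, row 8 the full network.
#'
#' @param width channel multiplier passed to every [model_spec()].
#' @param seed initialization seed shared by all variants.
#' @return List of 8 elements, each `list(spec, label)`.
#' @export
ablation_grid <- function(width = 1, seed = 11L) {
  toggles <- list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                  c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE),
                  c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
                  c(FALSE, TRUE, TRUE), c(TRUE, TRUE, TRUE))
  lapply(seq_along(toggles), function(i) {
    t <- toggles[[i]]
    list(spec = model_spec(use_spconv = t[1], use_cca = t[2],
                           use_cgb_down = t[3], width = width, seed = seed),
         label = as.character(i))
  })
}
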