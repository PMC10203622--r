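# Residual U-shaped backbone and the full coarse-to-fine cascade.
#
# Backbone: encoder with one residual block per resolution and stride-2
# convolutions for downsampling (channels double, 32 -> 64 -> 128 by
# default); decoder with bilinear x2 upsampling, concatenation skip
# connections and one residual block per resolution; 1x1 convolution +
# sigmoid head producing a per-pixel vessel probability.
#
# Cascade: both stages are exact twins taking a 4-channel input, a "prior"
# channel concatenated with the RGB image. The coarse stage's prior is all
# zeros (it has no earlier prediction); the fine stage's prior is the coarse
# probability map gated by the inter-stage attention module. This keeps the
# two backbones architecturally identical (equal parameter counts) while
# matching the cascade: fine input = concat(enhanced map, image).

residual_block <- function(in_ch, out_ch) {
  e <- new_module("resblock")
  e$conv1 <- layer_conv(in_ch, out_ch, 3L, pad = 1L, bias = FALSE)
  e$bn1 <- layer_bn(out_ch)
  e$relu1 <- layer_relu()
  e$conv2 <- layer_conv(out_ch, out_ch, 3L, pad = 1L, bias = FALSE)
  e$bn2 <- layer_bn(out_ch)
  e$relu_out <- layer_relu()
  e$project <- in_ch != out_ch
  e$children <- list(e$conv1, e$bn1, e$conv2, e$bn2)
  if (e$project) {
    e$sc_conv <- layer_conv(in_ch, out_ch, 1L, bias = FALSE)
    e$sc_bn <- layer_bn(out_ch)
    e$children <- c(e$children, list(e$sc_conv, e$sc_bn))
  }
  e$forward <- function(x, training = TRUE) {
    m <- e$bn2$forward(
      e$conv2$forward(
        e$relu1$forward(
          e$bn1$forward(e$conv1$forward(x, training), training), training),
        training), training)
    s <- if (e$project)
      e$sc_bn$forward(e$sc_conv$forward(x, training), training) else x
    e$relu_out$forward(m + s, training)
  }
  e$backward <- function(dout) {
    d <- e$relu_out$backward(dout)
    dx_main <- e$conv1$backward(
      e$bn1$backward(
        e$relu1$backward(
          e$conv2$backward(e$bn2$backward(d)))))
    dx_sc <- if (e$project) e$sc_conv$backward(e$sc_bn$backward(d)) else d
    dx_main + dx_sc
  }
  e
}

#' Create a residual U-shaped backbone
#'
#' Encoder-decoder with two stride-2 downsampling stages, residual
#' convolution blocks at every resolution, bilinear upsampling and
#' concatenation skip connections, ending in a 1x1 convolution and sigmoid.
#' Weights use Kaiming-style initialization drawn from the caller's RNG
#' scope (seed the surrounding call, e.g. via the cascade constructor).
#'
#' @param in_channels input channel count.
#' @param base_channels channels at full resolution; doubled at each of the
#'   two downsampling stages (default 32 giving the 32/64/128 schedule).
#' @return a backbone module for [backbone_forward()].
#' @export
backbone_new <- function(in_channels, base_channels = 32L) {
  stopifnot(in_channels >= 1L, base_channels >= 1L)
  c1 <- as.integer(base_channels); c2 <- 2L * c1; c3 <- 4L * c1
  e <- new_module("backbone")
  e$chans <- c(c1, c2, c3)
  e$enc1 <- residual_block(in_channels, c1)
  e$down1 <- layer_seq(layer_conv(c1, c2, 3L, stride = 2L, pad = 1L,
                                  bias = FALSE),
                       layer_bn(c2), layer_relu())
  e$enc2 <- residual_block(c2, c2)
  e$down2 <- layer_seq(layer_conv(c2, c3, 3L, stride = 2L, pad = 1L,
                                  bias = FALSE),
                       layer_bn(c3), layer_relu())
  e$bott <- residual_block(c3, c3)
  e$up1 <- layer_upsample2x()
  e$dec1 <- residual_block(c3 + c2, c2)
  e$up2 <- layer_upsample2x()
  e$dec2 <- residual_block(c2 + c1, c1)
  e$head <- layer_conv(c1, 1L, 1L, bias = TRUE)
  e$sig <- layer_sigmoid()
  e$children <- list(e$enc1, e$down1, e$enc2, e$down2, e$bott,
                     e$dec1, e$dec2, e$head)
  e$forward <- function(x, training = TRUE) {
    d <- dim(x)
    if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
      stop("input height and width must be divisible by 4 ",
           "(two stride-2 stages); got ", d[1], "x", d[2])
    e1 <- e$enc1$forward(x, training)
    e2 <- e$enc2$forward(e$down1$forward(e1, training), training)
    b <- e$bott$forward(e$down2$forward(e2, training), training)
    dd1 <- e$dec1$forward(cat_channels(e$up1$forward(b, training), e2),
                          training)
    dd2 <- e$dec2$forward(cat_channels(e$up2$forward(dd1, training), e1),
                          training)
    logits <- e$head$forward(dd2, training)
    list(prob = e$sig$forward(logits, training), logits = logits)
  }
  e$backward <- function(dprob, dlogits = NULL) {
    dlog <- e$sig$backward(dprob)
    if (!is.null(dlogits)) dlog <- dlog + dlogits
    dd2 <- e$head$backward(dlog)
    dcat2 <- e$dec2$backward(dd2)
    sp2 <- split_channels(dcat2, 2L * e$chans[1])  # up2 carries c2 channels
    de1_skip <- sp2$rest
    ddd1 <- e$up2$backward(sp2$first)
    dcat1 <- e$dec1$backward(ddd1)
    sp1 <- split_channels(dcat1, e$chans[3])       # up1 carries c3 channels
    de2_skip <- sp1$rest
    db <- e$up1$backward(sp1$first)
    dd2in <- e$bott$backward(db)
    de2 <- e$down2$backward(dd2in) + de2_skip
    dd1in <- e$enc2$backward(de2)
    de1 <- e$down1$backward(dd1in) + de1_skip
    e$enc1$backward(de1)
  }
  e
}

#' Run a backbone forward
#'
#' @param backbone module from [backbone_new()].
#' @param x input array (H, W, C) or (H, W, C, N); H and W must be divisible
#'   by 4.
#' @param training batch-norm mode.
#' @return list with `prob` (probability map, (H, W, 1, N), values in (0,1))
#'   and `logits` (pre-sigmoid map of the same shape).
#' @export
backbone_forward <- function(backbone, x, training = FALSE) {
  backbone$forward(as_t4(x), training)
}

#' Network configuration for the cascade
#'
#' @param in_channels image channels (3 for RGB fundus photographs). Each
#'   backbone additionally receives one prior channel (zero for the coarse
#'   stage, the attention-gated coarse map for the fine stage), so the stages
#'   are exact twins.
#' @param base_channels full-resolution channel count; the schedule is
#'   `base * c(1, 2, 4)` across the two downsampling stages (default
#'   32/64/128).
#' @param dilation_rates dilation rates of the attention branches.
#' @param use_cascade enable the fine stage (off = single-backbone baseline).
#' @param use_isam gate the coarse map through the attention module before
#'   concatenation (off = plain concatenation).
#' @param use_aux_supervision attach the auxiliary loss to the coarse map.
#' @param seed integer seed for weight initialization.
#' @return a `network_config` list.
#' @export
network_config <- function(in_channels = 3L, base_channels = 32L,
                           dilation_rates = c(1L, 2L, 3L),
                           use_cascade = TRUE, use_isam = TRUE,
                           use_aux_supervision = TRUE, seed = 1L) {
  cfg <- list(in_channels = as.integer(in_channels),
              base_channels = as.integer(base_channels),
              channel_schedule = as.integer(base_channels) * c(1L, 2L, 4L),
              n_down = 2L,
              dilation_rates = as.integer(dilation_rates),
              use_cascade = isTRUE(use_cascade),
              use_isam = isTRUE(use_isam),
              use_aux_supervision = isTRUE(use_aux_supervision),
              seed = as.integer(seed))
  if (cfg$in_channels < 1L || cfg$base_channels < 1L)
    stop("channel counts must be positive")
  if (any(cfg$dilation_rates < 1L)) stop("dilation rates must be positive")
  class(cfg) <- "network_config"
  cfg
}

#' Build the attention-guided cascaded network
#'
#' Constructs the coarse backbone, the inter-stage attention module and the
#' fine backbone from a [network_config()]; all weights are initialized
#' deterministically from `config$seed`.
#'
#' @param config a [network_config()].
#' @return a cascade model for [agc_forward()].
#' @export
agc_new <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  e <- new_module("agcnet")
  e$config <- config
  with_seed(config$seed, {
    e$coarse <- backbone_new(config$in_channels + 1L, config$base_channels)
    e$isam <- isam_new(config$dilation_rates)
    e$fine <- backbone_new(config$in_channels + 1L, config$base_channels)
  })
  e$children <- if (config$use_cascade) {
    if (config$use_isam) list(e$coarse, e$isam, e$fine)
    else list(e$coarse, e$fine)
  } else list(e$coarse)
  e
}

#' Forward pass of the full cascade
#'
#' The image (with a zero prior channel) passes through the coarse backbone;
#' its probability map is gated by the attention module and concatenated with
#' the image as the fine stage's input. Ablation switches in the config turn
#' the fine stage (`use_cascade`) or the attention gate (`use_isam`) off.
#'
#' @param model cascade from [agc_new()].
#' @param image array (H, W, C) or (H, W, C, N); H, W divisible by 4.
#' @param training batch-norm mode.
#' @return list of class `agc_output`: `coarse` and `fine` probability maps
#'   ((H, W, 1, N), in (0,1); `fine == coarse` when the cascade is off) and
#'   `attention` (attention map, or `NULL` when unused).
#' @export
agc_forward <- function(model, image, training = FALSE) {
  cfg <- model$config
  x <- as_t4(image)
  d <- dim(x)
  if (d[3] != cfg$in_channels)
    stop("expected ", cfg$in_channels, " image channels, got ", d[3])
  prior0 <- array(0, c(d[1], d[2], 1L, d[4]))
  coarse <- model$coarse$forward(cat_channels(prior0, x), training)
  if (!cfg$use_cascade) {
    out <- list(coarse = coarse$prob, fine = coarse$prob, attention = NULL)
    class(out) <- "agc_output"
    return(out)
  }
  if (cfg$use_isam) {
    gated <- model$isam$forward(coarse$prob, training)
    enh <- gated$f_out
    att <- gated$attention
  } else {
    enh <- coarse$prob
    att <- NULL
  }
  fine <- model$fine$forward(cat_channels(enh, x), training)
  out <- list(coarse = coarse$prob, fine = fine$prob, attention = att)
  class(out) <- "agc_output"
  out
}

# Backward pass through the whole cascade. dfine / dcoarse are gradients of
# the loss w.r.t. the fine and coarse probability maps ((H,W,1,N), either may
# be zero). Gradients reach the coarse backbone through both the cascade and
# the auxiliary path. Returns the gradient w.r.t. the image (rarely needed).
agc_backward <- function(model, dfine, dcoarse = NULL) {
  cfg <- model$config
  if (is.null(dcoarse)) dcoarse <- zeros_like(dfine)
  if (!cfg$use_cascade)
    return(model$coarse$backward(dfine + dcoarse))
  dxf <- model$fine$backward(dfine)
  sp <- split_channels(dxf, 1L)
  dpc_cascade <- if (cfg$use_isam) model$isam$backward(sp$first) else sp$first
  dximg_fine <- sp$rest
  dxc <- model$coarse$backward(dpc_cascade + dcoarse)
  split_channels(dxc, 1L)$rest + dximg_fine
}

# ---- checkpointing --------------------------------------------------------

# All module environments in a deterministic traversal order.
collect_modules <- function(module) {
  out <- list(module)
  for (ch in module$children) out <- c(out, collect_modules(ch))
  out
}

model_state <- function(model) {
  lapply(collect_modules(model), function(m) {
    s <- list(params = m$params)
    if (m$type == "bn")
      s$buffers <- list(running_mean = m$running_mean,
                        running_var = m$running_var)
    s
  })
}

load_model_state <- function(model, state) {
  mods <- collect_modules(model)
  if (length(mods) != length(state))
    stop("checkpoint does not match the model architecture")
  for (i in seq_along(mods)) {
    mods[[i]]$params <- state[[i]]$params
    if (!is.null(state[[i]]$buffers)) {
      mods[[i]]$running_mean <- state[[i]]$buffers$running_mean
      mods[[i]]$running_var <- state[[i]]$buffers$running_var
    }
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the network configuration, so [load_checkpoint()]
#' rebuilds the architecture and restores weights and batch-norm statistics.
#'
#' @param model cascade model.
#' @param path file path (`.rds`).
#' @return `save_checkpoint` the path, invisibly; `load_checkpoint` a model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- agc_new(ck$config)
  load_model_state(model, ck$state)
}
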