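# Inter-stage attention module (ISAM): a multi-scale spatial attention gate.
# Channel-wise average and max pooling give two H x W descriptors; their
# concatenation passes through three parallel dilated 3x3 convolutions
# (rates 1, 2, 3 by default, 2 -> 1 channels each), the branch outputs are
# summed, batch-normalized and squashed by a sigmoid into an attention map
# in (0,1) that multiplicatively gates every channel of the input.

#' Channel-pooled spatial descriptors
#'
#' Per-pixel mean and maximum across the channel axis, the two H x W x 1
#' descriptors fed to the attention branches.
#'
#' @param f_in feature map, array (H, W, C) or (H, W, C, N), C >= 1.
#' @return list with `f_avg` and `f_max`, each (H, W, 1, N).
#' @export
spatial_descriptors <- function(f_in) {
  x <- as_t4(f_in)
  d <- dim(x)
  if (d[3] < 1L) stop("feature map needs at least one channel")
  p <- pool_channels(x)
  list(f_avg = p$avg, f_max = p$max)
}

# Internal pooling with the caches backward needs (argmax of the max pool).
pool_channels <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- aperm(x, c(1, 2, 4, 3)); dim(xp) <- c(H * W * N, C)
  avg <- rowMeans(xp)
  mx <- xp[, 1]
  if (C > 1L) for (cc in 2:C) mx <- pmax(mx, xp[, cc])
  amax <- max.col(xp, ties.method = "first")
  shape <- function(v) {
    dim(v) <- c(H, W, N, 1L)
    aperm(v, c(1, 2, 4, 3))
  }
  list(avg = shape(avg), max = shape(mx), amax = amax, dims = d)
}

pool_channels_backward <- function(davg, dmax, cache) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  M <- H * W * N
  flat <- function(v) { v <- aperm(v, c(1, 2, 4, 3)); dim(v) <- NULL; v }
  dxp <- matrix(flat(davg) / C, M, C)            # mean spreads evenly
  dmx <- flat(dmax)                              # max routes to the argmax
  idx <- cbind(seq_len(M), cache$amax)
  dxp[idx] <- dxp[idx] + dmx
  dim(dxp) <- c(H, W, N, C)
  aperm(dxp, c(1, 2, 4, 3))
}

#' Create an inter-stage attention module
#'
#' @param dilation_rates integer dilation rates of the parallel 3x3 branches
#'   (default `c(1, 2, 3)`); padding equals the rate so H x W is preserved.
#'   The branches are independent (no weight sharing) and bias-free (batch
#'   normalization follows the sum).
#' @return an attention module usable with [isam_forward()].
#' @export
isam_new <- function(dilation_rates = c(1L, 2L, 3L)) {
  if (length(dilation_rates) < 1L || any(dilation_rates < 1L))
    stop("dilation rates must be positive integers")
  e <- new_module("isam")
  e$rates <- as.integer(dilation_rates)
  e$branches <- lapply(e$rates, function(r)
    layer_conv(2L, 1L, 3L, stride = 1L, pad = r, dilation = r, bias = FALSE))
  e$bn <- layer_bn(1L)
  e$sig <- layer_sigmoid()
  e$children <- c(e$branches, list(e$bn))
  e$forward <- function(x, training = TRUE) {
    x <- as_t4(x)
    pc <- pool_channels(x)
    e$cache_pool <- pc
    e$cache_x <- x
    desc <- cat_channels(pc$avg, pc$max)
    e$cache_desc <- desc
    s <- NULL
    for (br in e$branches) {
      o <- br$forward(desc, training)
      s <- if (is.null(s)) o else s + o
    }
    att <- e$sig$forward(e$bn$forward(s, training), training)
    e$cache_att <- att
    d <- dim(x)
    out <- x
    for (cc in seq_len(d[3])) out[, , cc, ] <- x[, , cc, ] * att[, , 1L, ]
    list(f_out = out, attention = att)
  }
  e$backward <- function(dfout, datt_extra = NULL) {
    x <- e$cache_x; att <- e$cache_att
    d <- dim(x)
    datt <- array(0, dim(att))
    dx <- dfout
    for (cc in seq_len(d[3])) {
      datt[, , 1L, ] <- datt[, , 1L, ] + dfout[, , cc, ] * x[, , cc, ]
      dx[, , cc, ] <- dfout[, , cc, ] * att[, , 1L, ]
    }
    if (!is.null(datt_extra)) datt <- datt + datt_extra
    ds <- e$bn$backward(e$sig$backward(datt))
    ddesc <- NULL
    for (br in e$branches) {
      g <- br$backward(ds)
      ddesc <- if (is.null(ddesc)) g else ddesc + g
    }
    sp <- split_channels(ddesc, 1L)
    dx + pool_channels_backward(sp$first, sp$rest, e$cache_pool)
  }
  e
}

#' Apply the inter-stage attention module
#'
#' @param isam module from [isam_new()].
#' @param f_in feature map (H, W, C) or (H, W, C, N). At the cascade point of
#'   the full network this is the coarse stage's 1-channel probability map,
#'   but the module accepts any C.
#' @param training use batch statistics (`TRUE`) or running averages in the
#'   batch-normalization step.
#' @return list with `f_out` (gated features, same shape as `f_in`) and
#'   `attention` (the H x W x 1 x N attention map, values in (0,1)).
#' @export
isam_forward <- function(isam, f_in, training = FALSE) {
  isam$forward(f_in, training)
}
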