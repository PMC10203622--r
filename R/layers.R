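# Minimal define-by-run layer framework. Each layer is an environment holding
# parameters, gradients and a cache; forward() stores what backward() needs.
# Every graph node is used at most once per step, so backward() assigns (not
# accumulates) parameter gradients.

new_module <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$children <- list()
  class(e) <- "agc_module"
  e
}

#' Number of trainable parameters of a module
#'
#' Counts every entry of every parameter array of the module and, recursively,
#' of its children. Used e.g. to verify that the coarse and fine backbones are
#' exact architectural twins.
#'
#' @param module a network module (backbone, attention module, full cascade).
#' @return integer parameter count.
#' @export
n_parameters <- function(module) {
  n <- sum(vapply(module$params, length, 0L))
  for (ch in module$children) n <- n + n_parameters(ch)
  as.integer(n)
}

# Flat list of (env, name) references to every parameter, for the optimizer.
collect_parameters <- function(module) {
  out <- lapply(names(module$params), function(nm) list(env = module, name = nm))
  for (ch in module$children) out <- c(out, collect_parameters(ch))
  out
}

# ---- convolution ----------------------------------------------------------

layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, dilation = 1L,
                       bias = TRUE, init_gain = 2) {
  e <- new_module("conv")
  e$stride <- as.integer(stride); e$pad <- as.integer(pad)
  e$dilation <- as.integer(dilation); e$bias <- bias
  fan_in <- k * k * in_ch
  e$params$W <- array(rnorm(k * k * in_ch * out_ch, 0, sqrt(init_gain / fan_in)),
                      c(k, k, in_ch, out_ch))
  if (bias) e$params$b <- numeric(out_ch)
  e$forward <- function(x, training = TRUE) {
    e$cache_x <- x
    .cpp_conv2d_fwd(x, e$params$W, if (bias) e$params$b else NULL,
                    e$stride, e$pad, e$dilation)
  }
  e$backward <- function(dout) {
    g <- .cpp_conv2d_bwd(e$cache_x, e$params$W, dout,
                         e$stride, e$pad, e$dilation, bias)
    e$grads$W <- g$dw
    if (bias) e$grads$b <- g$db
    g$dx
  }
  e
}

# ---- batch normalization --------------------------------------------------

layer_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  e <- new_module("bn")
  e$momentum <- momentum; e$eps <- eps
  e$params$gamma <- rep(1, ch)
  e$params$beta <- rep(0, ch)
  e$running_mean <- rep(0, ch)
  e$running_var <- rep(1, ch)
  e$forward <- function(x, training = TRUE) {
    d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
    xp <- aperm(x, c(1, 2, 4, 3)); dim(xp) <- c(H * W * N, C)
    M <- nrow(xp)
    if (training) {
      mu <- colMeans(xp)
      xc <- xp - rep(mu, each = M)
      v <- colMeans(xc * xc)
      e$running_mean <- (1 - e$momentum) * e$running_mean + e$momentum * mu
      e$running_var <- (1 - e$momentum) * e$running_var + e$momentum * v
    } else {
      mu <- e$running_mean
      v <- e$running_var
      xc <- xp - rep(mu, each = M)
    }
    invstd <- 1 / sqrt(v + e$eps)
    xhat <- xc * rep(invstd, each = M)
    y <- xhat * rep(e$params$gamma, each = M) + rep(e$params$beta, each = M)
    e$cache <- list(xhat = xhat, invstd = invstd, M = M, dims = d,
                    training = training)
    dim(y) <- c(H, W, N, C)
    aperm(y, c(1, 2, 4, 3))
  }
  e$backward <- function(dout) {
    cc <- e$cache; d <- cc$dims; M <- cc$M; C <- d[3]
    dy <- aperm(dout, c(1, 2, 4, 3)); dim(dy) <- c(M, C)
    e$grads$gamma <- colSums(dy * cc$xhat)
    e$grads$beta <- colSums(dy)
    dxhat <- dy * rep(e$params$gamma, each = M)
    if (cc$training) {
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * cc$xhat)
      dx <- (dxhat - rep(m1, each = M) - cc$xhat * rep(m2, each = M)) *
        rep(cc$invstd, each = M)
    } else {
      dx <- dxhat * rep(cc$invstd, each = M)
    }
    dim(dx) <- c(d[1], d[2], d[4], C)
    aperm(dx, c(1, 2, 4, 3))
  }
  e
}

# ---- pointwise activations ------------------------------------------------

layer_relu <- function() {
  e <- new_module("relu")
  e$forward <- function(x, training = TRUE) {
    e$cache_pos <- x > 0
    x * e$cache_pos
  }
  e$backward <- function(dout) dout * e$cache_pos
  e
}

layer_sigmoid <- function() {
  e <- new_module("sigmoid")
  e$forward <- function(x, training = TRUE) {
    y <- 1 / (1 + exp(-x))
    e$cache_y <- y
    y
  }
  e$backward <- function(dout) dout * e$cache_y * (1 - e$cache_y)
  e
}

# ---- bilinear x2 upsampling ----------------------------------------------

layer_upsample2x <- function() {
  e <- new_module("upsample2x")
  e$forward <- function(x, training = TRUE) {
    e$cache_hw <- dim(x)[1:2]
    .cpp_upsample2x_fwd(x)
  }
  e$backward <- function(dout)
    .cpp_upsample2x_bwd(dout, e$cache_hw[1], e$cache_hw[2])
  e
}

# ---- sequential composition ----------------------------------------------

layer_seq <- function(...) {
  e <- new_module("seq")
  e$children <- list(...)
  e$forward <- function(x, training = TRUE) {
    for (ch in e$children) x <- ch$forward(x, training)
    x
  }
  e$backward <- function(dout) {
    for (ch in rev(e$children)) dout <- ch$backward(dout)
    dout
  }
  e
}

# ---- Adam -----------------------------------------------------------------

# Standard Adam with bias correction; state lives beside each parameter.
adam_new <- function(param_refs, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$refs <- param_refs
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(param_refs, function(r) 0 * r$env$params[[r$name]])
  st$v <- lapply(param_refs, function(r) 0 * r$env$params[[r$name]])
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$refs)) {
    r <- st$refs[[i]]
    g <- r$env$grads[[r$name]]
    if (is.null(g)) next
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g * g
    mhat <- st$m[[i]] / bc1
    vhat <- st$v[[i]] / bc2
    r$env$params[[r$name]] <- r$env$params[[r$name]] -
      st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  invisible(st)
}
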