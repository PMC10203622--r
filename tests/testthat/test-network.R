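test_that("residual block reduces to ReLU(x) when the main path is zeroed", {
  blk <- agcnet:::with_seed(1, agcnet:::residual_block(4L, 4L))
  blk$conv1$params$W[] <- 0
  blk$conv2$params$W[] <- 0
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1))
  out <- blk$forward(x, training = FALSE)
  expect_equal(out, pmax(x, 0))
})

test_that("channel-changing residual block projects the shortcut", {
  blk <- agcnet:::with_seed(2, agcnet:::residual_block(4L, 8L))
  expect_true(blk$project)
  x <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 2))
  out <- blk$forward(x, training = TRUE)
  expect_equal(dim(out), c(6, 6, 8, 2))
})

test_that("residual block equals a hand-composed conv/BN/ReLU oracle", {
  blk <- agcnet:::with_seed(3, agcnet:::residual_block(2L, 2L))
  set.seed(4)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  out <- blk$forward(x, training = FALSE)
  bn_eval <- function(v, bn) {
    for (cc in seq_along(bn$params$gamma))
      v[, , cc, ] <- (v[, , cc, ] - bn$running_mean[cc]) /
        sqrt(bn$running_var[cc] + bn$eps) * bn$params$gamma[cc] +
        bn$params$beta[cc]
    v
  }
  h <- oracle_conv(x, blk$conv1$params$W, pad = 1)
  h <- pmax(bn_eval(h, blk$bn1), 0)
  h <- bn_eval(oracle_conv(h, blk$conv2$params$W, pad = 1), blk$bn2)
  expect_equal(out, pmax(h + x, 0), tolerance = 1e-5)
})

test_that("backbone maps any valid size to a same-size probability map", {
  bb <- agcnet:::with_seed(5, backbone_new(3L, 4L))
  x <- array(runif(16 * 20 * 3), c(16, 20, 3))
  out <- backbone_forward(bb, x)
  expect_equal(dim(out$prob), c(16, 20, 1, 1))
  expect_true(all(out$prob > 0 & out$prob < 1))
  # eval-mode forward passes are deterministic
  expect_identical(out$prob, backbone_forward(bb, x)$prob)
  expect_error(backbone_forward(bb, array(0, c(15, 20, 3))), "divisible by 4")
})

test_that("cascade outputs keep the input resolution and expose attention", {
  model <- agc_new(network_config(base_channels = 4, seed = 6))
  x <- array(runif(24 * 24 * 3), c(24, 24, 3))
  out <- agc_forward(model, x)
  expect_equal(dim(out$coarse), c(24, 24, 1, 1))
  expect_equal(dim(out$fine), c(24, 24, 1, 1))
  expect_equal(dim(out$attention), c(24, 24, 1, 1))
  expect_true(all(out$attention > 0 & out$attention < 1))
})

test_that("cascade off returns the coarse map as fine (baseline ablation)", {
  model <- agc_new(network_config(base_channels = 4, use_cascade = FALSE,
                                  seed = 7))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  out <- agc_forward(model, x)
  expect_identical(out$fine, out$coarse)
  expect_null(out$attention)
})

test_that("isam off concatenates the raw coarse map (CD+AS ablation)", {
  cfg <- network_config(base_channels = 4, use_isam = FALSE, seed = 8)
  model <- agc_new(cfg)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  out <- agc_forward(model, x)
  expect_null(out$attention)
  expect_false(identical(out$fine, out$coarse))
})

test_that("coarse and fine backbones are exact parameter twins", {
  model <- agc_new(network_config(base_channels = 8, seed = 9))
  expect_identical(n_parameters(model$coarse), n_parameters(model$fine))
})

test_that("gradients reach the coarse stage through cascade and aux paths", {
  model <- agc_new(network_config(base_channels = 4, seed = 10))
  set.seed(11)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  mask <- matrix(rbinom(256, 1, 0.2), 16, 16)
  grad_norm_after <- function(lambda) {
    out <- agc_forward(model, x, training = TRUE)
    sl <- total_supervised_loss(out$fine[, , 1, 1], out$coarse[, , 1, 1],
                                mask, lambda_aux = lambda, return_grad = TRUE)
    agcnet:::agc_backward(model,
                          array(sl$grad_fine, c(16, 16, 1, 1)),
                          array(sl$grad_coarse, c(16, 16, 1, 1)))
    sum(abs(model$coarse$enc1$conv2$grads$W))
  }
  expect_gt(grad_norm_after(1.0), 0)   # both paths
  expect_gt(grad_norm_after(0), 0)     # cascade only
})

test_that("checkpoints restore weights, stats and outputs exactly", {
  model <- agc_new(network_config(base_channels = 4, seed = 12))
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  before <- agc_forward(model, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  restored <- load_checkpoint(path)
  after <- agc_forward(restored, x)
  expect_identical(before$fine, after$fine)
  expect_identical(before$coarse, after$coarse)
})

test_that("the six ablation variants are expressible through the config", {
  grid <- ablation_grid(network_config(base_channels = 4, seed = 1))
  expect_named(grid, c("baseline", "+CD", "+CD+AS", "+CD+AS+ISAM",
                       "+CD+AS+PIBL", "full"))
  expect_false(grid$baseline$model_cfg$use_cascade)
  expect_equal(grid$baseline$loss, "ce")
  expect_true(grid$full$model_cfg$use_isam)
  expect_equal(grid$full$loss, "pib")
  expect_equal(grid[["+CD+AS+PIBL"]]$loss, "pib")
  expect_false(grid[["+CD+AS+PIBL"]]$model_cfg$use_isam)
})
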