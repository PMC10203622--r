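test_that("channel descriptors are per-pixel mean and max", {
  # single channel: both descriptors are the input itself
  x1 <- array(rnorm(16), c(4, 4, 1))
  d <- spatial_descriptors(x1)
  expect_equal(as.numeric(d$f_avg), as.numeric(x1))
  expect_equal(as.numeric(d$f_max), as.numeric(x1))
  # constant input
  xc <- array(3.5, c(4, 4, 5))
  d <- spatial_descriptors(xc)
  expect_true(all(d$f_avg == 3.5) && all(d$f_max == 3.5))
  # random input against a per-pixel loop
  set.seed(3)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  d <- spatial_descriptors(x)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(d$f_avg[i, j, 1, 1], mean(x[i, j, ]))
    expect_equal(d$f_max[i, j, 1, 1], max(x[i, j, ]))
  }
})

test_that("attention output preserves shape and lies strictly in (0,1)", {
  set.seed(4)
  m <- agcnet:::with_seed(1, isam_new())
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  out <- isam_forward(m, x)
  expect_equal(dim(out$f_out), c(8, 8, 3, 1))
  expect_equal(dim(out$attention), c(8, 8, 1, 1))
  expect_true(all(out$attention > 0 & out$attention < 1))
})

test_that("zeroed branch kernels give attention exactly one half", {
  m <- agcnet:::with_seed(1, isam_new())
  for (br in m$branches) br$params$W[] <- 0
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  out <- isam_forward(m, x, training = FALSE)
  expect_true(all(out$attention == 0.5))
  expect_equal(out$f_out, agcnet:::as_t4(x) * 0.5)
})

test_that("fixed-weight forward matches a naive dilated-convolution oracle", {
  m <- agcnet:::with_seed(2, isam_new(c(1L, 2L, 3L)))
  set.seed(5)
  x <- array(rnorm(9 * 7 * 4), c(9, 7, 4, 1))
  out <- isam_forward(m, x, training = FALSE)
  # oracle: explicit pooling, three dilated convs, eval-mode BN, sigmoid
  H <- 9; W <- 7
  favg <- array(0, c(H, W, 1, 1)); fmax <- favg
  for (i in 1:H) for (j in 1:W) {
    favg[i, j, 1, 1] <- mean(x[i, j, , 1])
    fmax[i, j, 1, 1] <- max(x[i, j, , 1])
  }
  desc <- array(0, c(H, W, 2, 1))
  desc[, , 1, ] <- favg; desc[, , 2, ] <- fmax
  s <- array(0, c(H, W, 1, 1))
  for (k in 1:3)
    s <- s + oracle_conv(desc, m$branches[[k]]$params$W,
                         stride = 1, pad = k, dil = k)
  bn <- m$bn
  z <- (s - bn$running_mean) / sqrt(bn$running_var + bn$eps) *
    bn$params$gamma + bn$params$beta
  att <- 1 / (1 + exp(-z))
  expect_equal(out$attention, att, tolerance = 1e-5)
  for (cc in 1:4)
    expect_equal(out$f_out[, , cc, 1], x[, , cc, 1] * att[, , 1, 1],
                 tolerance = 1e-5)
})

test_that("attention can only attenuate feature magnitudes", {
  m <- agcnet:::with_seed(3, isam_new())
  x <- array(rnorm(10 * 10 * 2), c(10, 10, 2))
  out <- isam_forward(m, x)
  expect_true(all(abs(out$f_out) <= abs(agcnet:::as_t4(x)) + 1e-12))
})

test_that("a single-pixel perturbation reaches at most Chebyshev radius 3", {
  m <- agcnet:::with_seed(4, isam_new(c(1L, 2L, 3L)))
  set.seed(6)
  x <- array(rnorm(12 * 12 * 2), c(12, 12, 2, 1))
  a0 <- isam_forward(m, x, training = FALSE)$attention
  xp <- x; xp[6, 6, 1, 1] <- xp[6, 6, 1, 1] + 1
  a1 <- isam_forward(m, xp, training = FALSE)$attention
  delta <- abs(a1 - a0)[, , 1, 1]
  for (i in 1:12) for (j in 1:12)
    if (max(abs(i - 6), abs(j - 6)) > 3)
      expect_equal(delta[i, j], 0)
  expect_gt(max(delta), 0)
})

test_that("gradients flow to the input and to all branch kernels", {
  m <- agcnet:::with_seed(5, isam_new())
  set.seed(7)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  out <- m$forward(x, training = TRUE)
  dfout <- array(rnorm(length(out$f_out)), dim(out$f_out))
  dx <- m$backward(dfout)
  expect_gt(sum(abs(dx)), 0)
  for (br in m$branches) expect_gt(sum(abs(br$grads$W)), 0)
})

test_that("invalid dilation rates are rejected", {
  expect_error(isam_new(c(0L, 1L)), "positive")
  expect_error(isam_new(integer(0)), "positive|rates")
})
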