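test_that("an all-background mask gets weight exactly 1 everywhere", {
  w <- compute_pib_weights(matrix(0, 10, 10))
  expect_true(all(w$weights == 1.0))
})

test_that("hand-evaluated box counts give the printed weights", {
  # fully vesselled 5x5: centre sees num = 25 -> -25*0.04 + 2 = 1.00
  w <- compute_pib_weights(matrix(1, 5, 5))
  expect_equal(w$weights[3, 3], 1.00)
  expect_equal(w$num[3, 3], 25)
  # single isolated vessel pixel: itself num = 1 -> 1.96; a 4-neighbour
  # (background, one vessel in its box) -> 1.04
  m <- matrix(0, 11, 11); m[6, 6] <- 1
  w <- compute_pib_weights(m)
  expect_equal(w$weights[6, 6], 1.96)
  expect_equal(w$weights[6, 5], 1.04)
  expect_equal(w$weights[5, 6], 1.04)
  # far background untouched
  expect_equal(w$weights[1, 1], 1.00)
})

test_that("vectorized weights equal the nested-loop oracle on random masks", {
  set.seed(42)
  for (i in 1:100) {
    m <- matrix(rbinom(256, 1, runif(1, 0.05, 0.5)), 16, 16)
    got <- compute_pib_weights(m)$weights
    expect_equal(got, oracle_pib_weights(m), tolerance = 1e-12)
    expect_true(all(got >= 1.00 - 1e-12 & got <= 1.96 + 1e-12))
  }
})

test_that("weights order thin over thick vessels and near over far background", {
  # vessel pixel weight strictly decreases as the box fills up
  line1 <- matrix(0, 9, 9); line1[5, ] <- 1              # 1-px line
  band <- matrix(0, 9, 9); band[3:7, ] <- 1              # 5-px band
  w_line <- compute_pib_weights(line1)$weights[5, 5]
  w_band <- compute_pib_weights(band)$weights[5, 5]
  expect_gt(w_line, w_band)
  # background pixel weight strictly increases with nearby vessel count
  w_near <- compute_pib_weights(line1)$weights[6, 5]     # adjacent to line
  w_far <- compute_pib_weights(line1)$weights[1, 5]      # far away
  expect_gt(w_near, w_far)
})

test_that("unit-weight loss equals an independent cross-entropy loop", {
  set.seed(7)
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  p <- matrix(runif(64, 0.01, 0.99), 8, 8)
  ones <- matrix(1, 8, 8)
  expect_equal(pib_loss(p, m, ones), oracle_bce(p, m), tolerance = 1e-6)
})

test_that("uniform prediction 0.5 gives mean(weights) * log 2", {
  set.seed(8)
  m <- matrix(rbinom(144, 1, 0.25), 12, 12)
  w <- compute_pib_weights(m)
  p <- matrix(0.5, 12, 12)
  expect_equal(pib_loss(p, m, w), mean(w$weights) * log(2), tolerance = 1e-12)
})

test_that("a perfect prediction has (clamped) near-zero loss", {
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  expect_lt(pib_loss(m, m), 1e-6)
})

test_that("analytic loss gradient matches finite differences", {
  set.seed(9)
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  g <- pib_loss(p, m, return_grad = TRUE)$grad
  eps <- 1e-6
  for (idx in sample(64, 12)) {
    pp <- p; pp[idx] <- pp[idx] + eps
    pm <- p; pm[idx] <- pm[idx] - eps
    num <- (pib_loss(pp, m) - pib_loss(pm, m)) / (2 * eps)
    expect_equal(g[idx], num, tolerance = 1e-4)
  }
})

test_that("deep-supervision total combines main and auxiliary linearly", {
  set.seed(10)
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  pf <- matrix(runif(64, 0.05, 0.95), 8, 8)
  pc <- matrix(runif(64, 0.05, 0.95), 8, 8)
  sl <- total_supervised_loss(pf, pc, m, lambda_aux = 1.0)
  expect_equal(sl$total, sl$loss_main + 1.0 * sl$loss_aux)
  expect_equal(total_supervised_loss(pf, pc, m, lambda_aux = 0)$total,
               sl$loss_main)
  same <- total_supervised_loss(pf, pf, m, lambda_aux = 1.0)
  expect_equal(same$total, 2 * same$loss_main)
  # default trade-off weight is 1.0
  expect_equal(total_supervised_loss(pf, pc, m)$lambda_aux, 1.0)
})

test_that("invalid inputs are rejected", {
  expect_error(compute_pib_weights(matrix(0.5, 4, 4)), "binary")
  expect_error(pib_loss(matrix(0.5, 4, 4), matrix(0, 4, 5)), "differ")
  expect_error(pib_loss(matrix(0.5, 4, 4), matrix(2, 4, 4)), "binary")
})

test_that("sum reduction and custom constants are honoured", {
  m <- matrix(rbinom(36, 1, 0.4), 6, 6)
  p <- matrix(runif(36, 0.1, 0.9), 6, 6)
  expect_equal(pib_loss(p, m, reduction = "sum"),
               pib_loss(p, m, reduction = "mean") * 36, tolerance = 1e-12)
  # wider box radius still counts the centre and clips at image borders
  w3 <- compute_pib_weights(matrix(1, 7, 7), box_radius = 3)
  expect_equal(w3$num[4, 4], 49)
})
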