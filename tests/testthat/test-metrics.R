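test_that("a perfect prediction scores 1 on every metric", {
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  r <- confusion_metrics(m, m)
  expect_equal(c(r$se, r$sp, r$acc, r$f1), c(1, 1, 1, 1))
})

test_that("a printed-size toy confusion reproduces the metric formulas", {
  # tp=1, fn=1, fp=0, tn=2
  mask <- matrix(c(1, 1, 0, 0), 2, 2)
  pred <- matrix(c(0.9, 0.1, 0.2, 0.3), 2, 2)
  r <- confusion_metrics(pred, mask)
  expect_equal(c(r$tp, r$fn, r$fp, r$tn), c(1, 1, 0, 2))
  expect_equal(r$se, 0.5)
  expect_equal(r$sp, 1.0)
  expect_equal(r$acc, 0.75)
  expect_equal(r$f1, 2 / 3)
})

test_that("degenerate single-class inputs yield NaN with a warning", {
  mask <- matrix(0, 4, 4)
  pred <- matrix(0.1, 4, 4)
  msgs <- capture_warnings(r <- confusion_metrics(pred, mask))
  expect_true(any(grepl("sensitivity", msgs)))
  expect_true(is.nan(r$se))
  expect_true(is.nan(r$f1))
  expect_equal(r$sp, 1)
  expect_error(roc_auc(pred, mask), "both classes")
})

test_that("raising the threshold never increases TP or FP", {
  set.seed(1)
  mask <- matrix(rbinom(100, 1, 0.3), 10, 10)
  pred <- matrix(runif(100), 10, 10)
  prev_tp <- Inf; prev_fp <- Inf
  for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    r <- confusion_metrics(pred, mask, threshold = th)
    expect_lte(r$tp, prev_tp)
    expect_lte(r$fp, prev_fp)
    prev_tp <- r$tp; prev_fp <- r$fp
  }
})

test_that("AUC equals the pairwise comparison oracle, ties included", {
  set.seed(2)
  for (i in 1:5) {
    mask <- matrix(rbinom(144, 1, 0.3), 12, 12)
    if (sum(mask) == 0 || sum(mask) == 144) next
    # discretized scores force ties
    pred <- matrix(round(runif(144), 1), 12, 12)
    r <- roc_auc(pred, mask)
    expect_equal(r$auc, oracle_auc(pred, mask), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent library implementation", {
  set.seed(6)
  mask <- matrix(rbinom(400, 1, 0.25), 20, 20)
  pred <- matrix(runif(400)^2, 20, 20)
  ours <- roc_auc(pred, mask)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(as.numeric(mask), as.numeric(pred),
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  mask <- matrix(rbinom(100, 1, 0.3), 10, 10)
  pred <- matrix(runif(100, 0.01, 0.99), 10, 10)
  a0 <- roc_auc(pred, mask)$auc
  expect_equal(roc_auc(pred^3, mask)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(log(pred), mask)$auc, a0, tolerance = 1e-12)
})

test_that("uninformative predictions give chance-level AUC", {
  set.seed(4)
  mask <- matrix(rbinom(4096, 1, 0.2), 64, 64)
  pred <- matrix(runif(4096), 64, 64)
  a <- roc_auc(pred, mask)$auc
  n_pos <- sum(mask); n_neg <- 4096 - n_pos
  expect_lt(abs(a - 0.5), 3 / sqrt(n_pos * n_neg) * sqrt(4096))
})

test_that("FOV restriction equals manual pre-masking", {
  set.seed(5)
  mask <- matrix(rbinom(256, 1, 0.3), 16, 16)
  pred <- matrix(runif(256), 16, 16)
  fov <- matrix(0, 16, 16); fov[4:13, 4:13] <- 1
  r_fov <- confusion_metrics(pred, mask, fov = fov)
  keep <- fov == 1
  r_man <- confusion_metrics(pred[keep], mask[keep])
  expect_equal(r_fov[c("tp", "fp", "fn", "tn", "se", "sp", "acc", "f1")],
               r_man[c("tp", "fp", "fn", "tn", "se", "sp", "acc", "f1")])
  a_fov <- roc_auc(pred, mask, fov = fov)$auc
  expect_equal(a_fov, roc_auc(pred[keep], mask[keep])$auc)
  expect_error(confusion_metrics(pred, mask, fov = matrix(0, 16, 16)),
               "empty")
})

test_that("the ROC curve is a valid staircase from (0,0) to (1,1)", {
  set.seed(7)
  mask <- matrix(rbinom(100, 1, 0.4), 10, 10)
  pred <- matrix(runif(100), 10, 10)
  cv <- roc_auc(pred, mask)$curve
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1); expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})
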