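# Training tests run at desk scale: 64x64 synthetic samples and a narrow
# (base 4) network so the whole file stays fast.

test_that("default schedule matches the published recipe", {
  tc <- train_config()
  expect_equal(tc$batch_size, 2L)
  expect_equal(tc$lr, 1e-3)
  expect_equal(tc$epochs, 200L)
  expect_equal(tc$lr_decay_epochs, c(150L, 190L))
  expect_equal(tc$lr_decay_factor, 0.1)
  expect_equal(tc$lambda_aux, 1.0)
  expect_equal(tc$optimizer, "adam")
  expect_error(train_config(epochs = 100), "smaller than the total")
  expect_error(train_config(lr = 0, epochs = 10,
                            lr_decay_epochs = integer(0)), "positive")
})

test_that("a short run reduces the training loss and logs both loss parts", {
  data <- tiny_data(8, 0)
  st <- train(network_config(base_channels = 4, seed = 1),
              train_config(epochs = 5, lr_decay_epochs = integer(0),
                           seed = 1),
              data)
  h <- st$history
  expect_equal(nrow(h), 5)
  expect_lt(h$train_loss[5], h$train_loss[1])
  # bookkeeping: total = main + 1.0 * aux at every epoch
  expect_equal(h$train_loss, h$train_loss_main + 1.0 * h$train_loss_aux,
               tolerance = 1e-10)
})

test_that("training is seed-deterministic on CPU", {
  data <- tiny_data(4, 2)
  run <- function() {
    st <- train(network_config(base_channels = 4, seed = 2),
                train_config(epochs = 2, lr_decay_epochs = integer(0),
                             seed = 3),
                data)
    st$history
  }
  expect_identical(run(), run())
})

test_that("learning-rate decay is applied at the scheduled epochs", {
  data <- tiny_data(2, 0)
  st <- train(network_config(base_channels = 4, seed = 4),
              train_config(epochs = 4, lr_decay_epochs = c(2L, 3L),
                           seed = 1, augment = FALSE),
              data)
  expect_equal(st$history$lr, 1e-3 * c(1, 1, 0.1, 0.01), tolerance = 1e-12)
})

test_that("an overfit tiny run reaches high accuracy on its training set", {
  data <- tiny_data(4, 0)
  st <- train(network_config(base_channels = 8, seed = 5),
              train_config(epochs = 35, lr_decay_epochs = integer(0),
                           seed = 1, augment = FALSE, select_by = "last"),
              data)
  ev <- evaluate(st$model, data$train, use_fov = FALSE)
  expect_gt(ev$report$acc, 0.95)
})

test_that("evaluation pads, predicts and crops back to the original size", {
  data <- generate_dataset(synthetic_spec(height = 60, width = 52, seed = 6),
                           2, 0)
  model <- agc_new(network_config(base_channels = 4, seed = 6))
  ev <- evaluate(model, data$train, use_fov = FALSE)
  expect_equal(dim(ev$pred[[1]]), c(60, 52))
  expect_equal(nrow(ev$per_image), 2)
  # evaluation is deterministic
  ev2 <- evaluate(model, data$train, use_fov = FALSE)
  expect_identical(ev$pred, ev2$pred)
})

test_that("the ablation harness produces one populated row per variant", {
  data <- tiny_data(4, 2)
  grid <- ablation_grid(network_config(base_channels = 4, seed = 7))
  tab <- run_ablation(grid[c("baseline", "full")],
                      train_config(epochs = 2, lr_decay_epochs = integer(0),
                                   seed = 1),
                      data)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$variant, c("baseline", "full"))
  expect_equal(tab$loss, c("ce", "pib"))
  expect_true(all(is.finite(tab$auc)))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
})

test_that("train state keeps the best epoch and restores its weights", {
  data <- tiny_data(4, 2)
  st <- train(network_config(base_channels = 4, seed = 8),
              train_config(epochs = 3, lr_decay_epochs = integer(0),
                           seed = 1),
              data)
  expect_true(st$best_epoch %in% 1:3)
  expect_equal(st$best_metric,
               max(st$history$test_auc, na.rm = TRUE), tolerance = 1e-12)
})
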