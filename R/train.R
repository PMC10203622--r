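# Training loop (Adam, step-decay schedule, online augmentation, deep
# supervision), best-epoch checkpointing, evaluation with the pad/crop
# convention, and the ablation harness.

#' Training configuration
#'
#' Defaults follow the published recipe: batch size 2, Adam with initial
#' learning rate 1e-3, 200 epochs with a x0.1 decay at epochs 150 and 190,
#' auxiliary-loss weight 1.0, online augmentation, best epoch selected on
#' test AUC.
#'
#' @param batch_size images per optimization step.
#' @param lr initial learning rate.
#' @param optimizer only `"adam"` is implemented.
#' @param epochs total training epochs.
#' @param lr_decay_epochs epochs at which the rate is multiplied by
#'   `lr_decay_factor`; must all be < `epochs`.
#' @param lr_decay_factor multiplicative decay.
#' @param lambda_aux weight of the auxiliary (coarse-stage) loss.
#' @param loss `"pib"` for pixel-importance-balance weights, `"ce"` for
#'   plain cross-entropy (all weights 1).
#' @param augment apply online augmentation to training samples.
#' @param aug an [augment_spec()].
#' @param eval_every evaluate on the test set every this many epochs.
#' @param select_by `"auc"` keeps the best-test-AUC epoch (optimistic
#'   protocol, kept for fidelity with the published setup); `"last"` keeps
#'   the final epoch.
#' @param seed master seed for shuffling and augmentation draws.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 2L, lr = 1e-3, optimizer = "adam",
                         epochs = 200L, lr_decay_epochs = c(150L, 190L),
                         lr_decay_factor = 0.1, lambda_aux = 1.0,
                         loss = c("pib", "ce"), augment = TRUE,
                         aug = augment_spec(), eval_every = 1L,
                         select_by = c("auc", "last"), seed = 1L) {
  loss <- match.arg(loss)
  select_by <- match.arg(select_by)
  if (lr <= 0) stop("learning rate must be positive")
  if (length(lr_decay_epochs) && any(lr_decay_epochs >= epochs))
    stop("decay epochs must be smaller than the total epoch count")
  if (optimizer != "adam") stop("only the adam optimizer is implemented")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 optimizer = optimizer, epochs = as.integer(epochs),
                 lr_decay_epochs = as.integer(lr_decay_epochs),
                 lr_decay_factor = lr_decay_factor,
                 lambda_aux = lambda_aux, loss = loss,
                 augment = isTRUE(augment), aug = aug,
                 eval_every = as.integer(eval_every),
                 select_by = select_by, seed = as.integer(seed)),
            class = "train_config")
}

sample_weights <- function(mask, kind) {
  if (kind == "pib") compute_pib_weights(mask)$weights
  else matrix(1, nrow(mask), ncol(mask))
}

stack_images <- function(samples) {
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], d[3], length(samples)))
  for (i in seq_along(samples)) x[, , , i] <- samples[[i]]$image
  x
}

#' Train the cascaded network
#'
#' Runs the full schedule with online augmentation (geometric transforms are
#' applied to image and mask together and loss weights are recomputed from
#' the augmented mask), logs train/test loss and test AUC per epoch, and
#' returns the model restored to the best epoch. Fully deterministic for a
#' fixed seed on CPU. A non-finite loss aborts with a diagnostic naming the
#' epoch and step.
#'
#' @param model_cfg a [network_config()].
#' @param train_cfg a [train_config()].
#' @param data list with `train` and `test` lists of `fundus_sample`.
#' @param verbose print a line per epoch.
#' @return object of class `agc_train_state`: list with `model` (weights of
#'   the selected epoch), `history` (per-epoch data.frame), `best_epoch`,
#'   `best_metric`, and the two configs.
#' @export
train <- function(model_cfg, train_cfg, data, verbose = FALSE) {
  stopifnot(inherits(model_cfg, "network_config"),
            inherits(train_cfg, "train_config"))
  if (length(data$train) == 0L) stop("training set is empty")
  model <- agc_new(model_cfg)
  opt <- adam_new(collect_parameters(model), lr = train_cfg$lr)
  n <- length(data$train)
  lambda <- if (model_cfg$use_aux_supervision) train_cfg$lambda_aux else 0
  history <- vector("list", train_cfg$epochs)
  best_metric <- -Inf; best_epoch <- NA_integer_; best_state <- NULL

  for (epoch in seq_len(train_cfg$epochs)) {
    opt$lr <- train_cfg$lr *
      train_cfg$lr_decay_factor^sum(epoch > train_cfg$lr_decay_epochs)
    order_idx <- with_seed(derive_seed(train_cfg$seed, epoch), sample(n))
    losses <- c(); mains <- c(); auxs <- c()
    step <- 0L
    for (b in split(order_idx, ceiling(seq_along(order_idx) /
                                         train_cfg$batch_size))) {
      step <- step + 1L
      batch <- lapply(seq_along(b), function(k) {
        s <- data$train[[b[k]]]
        if (train_cfg$augment)
          s <- augment(s, train_cfg$aug,
                       seed = derive_seed(train_cfg$seed,
                                          epoch * 1000L + b[k]))
        s
      })
      x <- stack_images(batch)
      out <- agc_forward(model, x, training = TRUE)
      N <- length(batch)
      dfine <- zeros_like(out$fine); dcoarse <- zeros_like(out$coarse)
      lt <- lm <- la <- 0
      for (k in seq_len(N)) {
        w <- sample_weights(batch[[k]]$mask, train_cfg$loss)
        sl <- total_supervised_loss(out$fine[, , 1L, k], out$coarse[, , 1L, k],
                                    batch[[k]]$mask, lambda_aux = lambda,
                                    weights = w, return_grad = TRUE)
        lt <- lt + sl$total / N; lm <- lm + sl$loss_main / N
        la <- la + sl$loss_aux / N
        dfine[, , 1L, k] <- sl$grad_fine / N
        dcoarse[, , 1L, k] <- sl$grad_coarse / N
      }
      if (!is.finite(lt))
        stop("training diverged: non-finite loss at epoch ", epoch,
             ", step ", step)
      agc_backward(model, dfine, dcoarse)
      adam_step(opt)
      losses <- c(losses, lt); mains <- c(mains, lm); auxs <- c(auxs, la)
    }
    test_loss <- NA_real_; test_auc <- NA_real_
    if (length(data$test) > 0L && epoch %% train_cfg$eval_every == 0L) {
      te <- eval_loss_auc(model, data$test, train_cfg$loss, lambda)
      test_loss <- te$loss; test_auc <- te$auc
    }
    history[[epoch]] <- data.frame(epoch = epoch, lr = opt$lr,
                                   train_loss = mean(losses),
                                   train_loss_main = mean(mains),
                                   train_loss_aux = mean(auxs),
                                   test_loss = test_loss,
                                   test_auc = test_auc)
    metric_now <- if (train_cfg$select_by == "auc" && is.finite(test_auc))
      test_auc else if (train_cfg$select_by == "last") epoch else NA_real_
    if (is.finite(metric_now) && metric_now >= best_metric) {
      best_metric <- metric_now
      best_epoch <- epoch
      best_state <- model_state(model)
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  test %.4f  auc %s", epoch,
                      mean(losses), test_loss,
                      ifelse(is.na(test_auc), "-", sprintf("%.4f", test_auc))))
  }
  if (!is.null(best_state)) load_model_state(model, best_state)
  else best_epoch <- train_cfg$epochs
  hist <- do.call(rbind, history)
  structure(list(model = model, history = hist, best_epoch = best_epoch,
                 best_metric = if (train_cfg$select_by == "auc")
                   best_metric else NA_real_,
                 model_cfg = model_cfg, train_cfg = train_cfg),
            class = "agc_train_state")
}

# Test-set loss and pooled AUC in eval mode (no augmentation, no padding:
# samples are assumed network-sized here; evaluate() handles padding).
eval_loss_auc <- function(model, samples, loss_kind, lambda) {
  x <- stack_images(samples)
  out <- agc_forward(model, x, training = FALSE)
  tot <- 0
  preds <- vector("list", length(samples))
  masks <- lapply(samples, `[[`, "mask")
  fovs <- lapply(samples, `[[`, "fov")
  for (k in seq_along(samples)) {
    w <- sample_weights(masks[[k]], loss_kind)
    sl <- total_supervised_loss(out$fine[, , 1L, k], out$coarse[, , 1L, k],
                                masks[[k]], lambda_aux = lambda, weights = w)
    tot <- tot + sl$total / length(samples)
    preds[[k]] <- out$fine[, , 1L, k]
  }
  pool <- pool_pixels(preds, masks, fovs)
  list(loss = tot, auc = roc_auc(pool$pred, pool$mask)$auc)
}

#' Evaluate a trained model on a set of samples
#'
#' Each image is zero-padded to the automatic square target
#' ([pad_spec_auto()]), run through the cascade in eval mode, and the
#' fine-stage probability map is cropped back to the original size before
#' computing metrics. Dataset-level metrics pool pixel counts over all
#' samples before forming ratios; per-image metrics are also returned.
#'
#' @param model a trained cascade (or an `agc_train_state`, or a checkpoint
#'   path).
#' @param samples list of `fundus_sample`.
#' @param threshold decision threshold for the confusion metrics.
#' @param use_fov restrict metrics to each sample's FOV mask when present.
#' @return list with `report` (pooled `agc_metrics` with `$auc`),
#'   `per_image` (data.frame) and `pred` (list of cropped probability maps).
#' @export
evaluate <- function(model, samples, threshold = 0.5, use_fov = TRUE) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "agc_train_state")) model <- model$model
  if (length(samples) == 0L) stop("no samples to evaluate")
  preds <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    img <- samples[[k]]$image
    d <- dim(img)
    ps <- pad_spec_auto(d[1], d[2])
    xp <- pad_to(img, ps)
    out <- agc_forward(model, xp, training = FALSE)
    preds[[k]] <- crop_back(out$fine[, , 1L, 1L], ps)
  }
  masks <- lapply(samples, `[[`, "mask")
  fovs <- if (use_fov) lapply(samples, `[[`, "fov") else NULL
  pool <- pool_pixels(preds, masks, fovs)
  rep_all <- confusion_metrics(pool$pred, pool$mask, threshold)
  rep_all$auc <- roc_auc(pool$pred, pool$mask)$auc
  per <- do.call(rbind, lapply(seq_along(samples), function(k) {
    f <- if (use_fov) samples[[k]]$fov else NULL
    m <- confusion_metrics(preds[[k]], masks[[k]], threshold, f)
    a <- roc_auc(preds[[k]], masks[[k]], f)$auc
    data.frame(sample = k, se = m$se, sp = m$sp, acc = m$acc, f1 = m$f1,
               auc = a)
  }))
  list(report = rep_all, per_image = per, pred = preds)
}

#' The six ablation configurations
#'
#' Variants of the network/loss lattice: single-backbone baseline with plain
#' cross-entropy; + cascade design (CD); + auxiliary supervision (AS); +
#' inter-stage attention (ISAM); + pixel-importance-balance loss (PIBL); and
#' the full configuration.
#'
#' @param base_cfg a [network_config()] supplying channels, rates and seed.
#' @return named list of `list(model_cfg, loss)` variants.
#' @export
ablation_grid <- function(base_cfg = network_config()) {
  mk <- function(cascade, isam, aux) {
    cfg <- base_cfg
    cfg$use_cascade <- cascade; cfg$use_isam <- isam
    cfg$use_aux_supervision <- aux
    cfg
  }
  list("baseline"      = list(model_cfg = mk(FALSE, FALSE, FALSE), loss = "ce"),
       "+CD"           = list(model_cfg = mk(TRUE, FALSE, FALSE), loss = "ce"),
       "+CD+AS"        = list(model_cfg = mk(TRUE, FALSE, TRUE), loss = "ce"),
       "+CD+AS+ISAM"   = list(model_cfg = mk(TRUE, TRUE, TRUE), loss = "ce"),
       "+CD+AS+PIBL"   = list(model_cfg = mk(TRUE, FALSE, TRUE), loss = "pib"),
       "full"          = list(model_cfg = mk(TRUE, TRUE, TRUE), loss = "pib"))
}

#' Run an ablation study
#'
#' Trains each variant under the same training configuration and data and
#' evaluates it on the test set.
#'
#' @param variants named list as produced by [ablation_grid()] (possibly a
#'   subset).
#' @param train_cfg a [train_config()]; its `loss` field is overridden per
#'   variant.
#' @param data list with `train` and `test` sample lists.
#' @param csv optional path: write the table as CSV.
#' @param verbose print per-epoch progress.
#' @return data.frame with one row per variant (SE/SP/ACC/F1/AUC).
#' @export
run_ablation <- function(variants, train_cfg, data, csv = NULL,
                         verbose = FALSE) {
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    tc <- train_cfg
    tc$loss <- v$loss
    st <- train(v$model_cfg, tc, data, verbose = verbose)
    ev <- evaluate(st$model, data$test)
    data.frame(variant = nm, loss = v$loss,
               se = ev$report$se, sp = ev$report$sp, acc = ev$report$acc,
               f1 = ev$report$f1, auc = ev$report$auc,
               best_epoch = st$best_epoch)
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

#' Plot per-epoch loss curves to a PNG
#'
#' @param state an `agc_train_state`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_history <- function(state, path) {
  h <- state$history
  grDevices::png(path, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  ylim <- range(c(h$train_loss, h$test_loss), na.rm = TRUE)
  plot(h$epoch, h$train_loss, type = "l", col = "blue", lwd = 2,
       xlab = "epoch", ylab = "loss", ylim = ylim, main = "training curves")
  if (any(is.finite(h$test_loss)))
    graphics::lines(h$epoch, h$test_loss, col = "orange", lwd = 2)
  graphics::legend("topright", bty = "n", col = c("blue", "orange"), lwd = 2,
                   legend = c("train", "test"))
  invisible(path)
}
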