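# Pixel-importance-balance (PIB) loss: weighted binary cross-entropy whose
# per-pixel weight is a linear function of the number of vessel pixels in the
# (2r+1)x(2r+1) box around the pixel (r = 2, i.e. a 5x5 box, by default).
# Vessel pixels:      weight = vessel_slope * num + vessel_intercept
# Background pixels:  weight = background_slope * num + background_intercept
# With the published constants (-0.04, 2) and (+0.04, 1) every weight lies in
# [1.00, 1.96]: thin-vessel pixels (few vessel neighbours) and background
# pixels hugging a vessel are emphasized, interiors of thick vessels and far
# background are not.

#' Per-pixel loss weights for the pixel-importance-balance loss
#'
#' For each pixel the number of vessel pixels (`num`) in the surrounding
#' `(2*box_radius+1)` square box -- the centre pixel included -- is counted;
#' cells of the box falling outside the image contribute zero. The weight is
#' then a decreasing linear function of `num` on vessel pixels and an
#' increasing one on background pixels, so thin vessels and vessel-adjacent
#' background dominate the loss rather than the vast far background.
#'
#' @param mask binary vessel mask (matrix, 1 = vessel, 0 = background).
#' @param box_radius box half-width in pixels; 2 gives the 5x5 box.
#' @param vessel_slope,vessel_intercept linear map `num -> weight` applied at
#'   vessel pixels (defaults -0.04 and 2).
#' @param background_slope,background_intercept linear map applied at
#'   background pixels (defaults +0.04 and 1).
#' @return an object of class `agc_weightmap`: list with `weights` (matrix,
#'   same shape as `mask`), `num` (the box counts) and the constants used.
#' @examples
#' m <- matrix(0, 8, 8); m[4, 3:6] <- 1
#' w <- compute_pib_weights(m)
#' range(w$weights)
#' @export
compute_pib_weights <- function(mask, box_radius = 2L,
                                vessel_slope = -0.04, vessel_intercept = 2,
                                background_slope = 0.04,
                                background_intercept = 1) {
  if (!is.matrix(mask)) mask <- as.matrix(mask)
  if (!is_binary(mask)) stop("mask must be binary (0/1)")
  r <- as.integer(box_radius)
  if (r < 0L) stop("box_radius must be >= 0")
  H <- nrow(mask); W <- ncol(mask)
  # Box count by summing the (2r+1)^2 shifted copies of a zero-padded mask;
  # out-of-image cells therefore contribute 0.
  padded <- matrix(0, H + 2L * r, W + 2L * r)
  padded[r + seq_len(H), r + seq_len(W)] <- mask
  num <- matrix(0, H, W)
  for (dy in -r:r) for (dx in -r:r)
    num <- num + padded[r + dy + seq_len(H), r + dx + seq_len(W)]
  weights <- ifelse(mask == 1,
                    vessel_slope * num + vessel_intercept,
                    background_slope * num + background_intercept)
  structure(list(weights = weights, num = num, box_radius = r,
                 vessel_slope = vessel_slope,
                 vessel_intercept = vessel_intercept,
                 background_slope = background_slope,
                 background_intercept = background_intercept),
            class = "agc_weightmap")
}

# Accept either an agc_weightmap or a bare matrix of weights.
resolve_weights <- function(weights, mask) {
  if (is.null(weights)) return(compute_pib_weights(mask)$weights)
  if (inherits(weights, "agc_weightmap")) return(weights$weights)
  weights
}

#' Pixel-importance-balance weighted cross-entropy
#'
#' Weighted binary cross-entropy between a probability map and a binary
#' vessel mask: each pixel contributes `weight * (-log p)` on vessel pixels
#' and `weight * (-log(1 - p))` on background pixels. Probabilities are
#' clamped to `[eps, 1 - eps]` before taking logs. The default reduction is
#' the mean over pixels, which keeps the loss scale independent of image /
#' pad size; `reduction = "sum"` gives the raw sum. With all weights equal to
#' one this is plain binary cross-entropy.
#'
#' @param pred probability map in (0,1), same shape as `mask`.
#' @param mask binary vessel mask.
#' @param weights optional `agc_weightmap` or weight matrix; computed from
#'   `mask` with the default constants when `NULL`.
#' @param reduction `"mean"` (default) or `"sum"` over pixels.
#' @param eps probability clamp before the log.
#' @param return_grad if `TRUE`, also return the analytic gradient of the
#'   loss with respect to `pred`.
#' @return the scalar loss, or (with `return_grad`) a list `loss`, `grad`.
#' @export
pib_loss <- function(pred, mask, weights = NULL, reduction = c("mean", "sum"),
                     eps = 1e-7, return_grad = FALSE) {
  reduction <- match.arg(reduction)
  if (!all(dim(pred) == dim(mask)))
    stop("pred and mask shapes differ: ", paste(dim(pred), collapse = "x"),
         " vs ", paste(dim(mask), collapse = "x"))
  if (!is_binary(mask)) stop("mask must be binary (0/1)")
  w <- resolve_weights(weights, mask)
  if (!all(dim(w) == dim(mask))) stop("weight map shape differs from mask")
  if (any(w <= 0)) stop("all loss weights must be positive")
  p <- clamp01(pred, eps)
  ce <- -(mask * log(p) + (1 - mask) * log(1 - p))
  loss <- if (reduction == "mean") mean(w * ce) else sum(w * ce)
  if (!return_grad) return(loss)
  # d/dp of w * ce; zero where the clamp is active (p saturated).
  g <- w * (-(mask / p) + (1 - mask) / (1 - p))
  g[pred <= eps | pred >= 1 - eps] <- 0
  if (reduction == "mean") g <- g / length(p)
  list(loss = loss, grad = g)
}

#' Deep-supervision total loss of the cascade
#'
#' The cascade is trained with a main loss on the fine-stage probability map
#' and an auxiliary loss on the coarse-stage (intermediate) map, both against
#' the same ground truth: `total = loss_main + lambda_aux * loss_aux`. The
#' weight map is computed once from the mask and shared by both terms.
#'
#' @param pred_fine,pred_coarse probability maps shaped like `mask`.
#' @param mask binary vessel mask.
#' @param lambda_aux trade-off weight of the auxiliary path (default 1.0).
#' @param weights optional precomputed weight map; `NULL` computes PIB
#'   weights from `mask`. Pass a matrix of ones for plain cross-entropy.
#' @param reduction,eps,return_grad as in [pib_loss()].
#' @return object of class `agc_suploss`: list with `loss_main`, `loss_aux`,
#'   `lambda_aux`, `total` and, with `return_grad`, `grad_fine`,
#'   `grad_coarse`.
#' @export
total_supervised_loss <- function(pred_fine, pred_coarse, mask,
                                  lambda_aux = 1.0, weights = NULL,
                                  reduction = "mean", eps = 1e-7,
                                  return_grad = FALSE) {
  w <- resolve_weights(weights, mask)
  main <- pib_loss(pred_fine, mask, w, reduction, eps, return_grad)
  aux <- pib_loss(pred_coarse, mask, w, reduction, eps, return_grad)
  if (return_grad) {
    out <- list(loss_main = main$loss, loss_aux = aux$loss,
                lambda_aux = lambda_aux,
                total = main$loss + lambda_aux * aux$loss,
                grad_fine = main$grad, grad_coarse = lambda_aux * aux$grad)
  } else {
    out <- list(loss_main = main, loss_aux = aux, lambda_aux = lambda_aux,
                total = main + lambda_aux * aux)
  }
  structure(out, class = "agc_suploss")
}
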