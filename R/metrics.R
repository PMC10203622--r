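# Pixel-level evaluation: confusion-matrix metrics at a threshold, ROC curve
# and AUC, with optional restriction to a field-of-view (FOV) mask.

#' Confusion-matrix segmentation metrics
#'
#' Pixels with `pred >= threshold` are called vessel. Sensitivity, specificity,
#' accuracy and F1 are computed as
#' `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`, `ACC = (TP+TN)/(TP+TN+FP+FN)`,
#' `F1 = 2TP/(2TP+FP+FN)`. When a ratio's denominator is zero (a class absent
#' from the evaluated region) that metric is `NaN` and a warning is raised.
#'
#' @param pred probability map, same shape as `mask`.
#' @param mask binary ground-truth vessel mask.
#' @param threshold decision threshold in (0,1), default 0.5.
#' @param fov optional binary field-of-view mask; pixels outside it are
#'   excluded from all counts.
#' @return object of class `agc_metrics`: list with counts `tp`, `fp`, `fn`,
#'   `tn` and metrics `se`, `sp`, `acc`, `f1`, plus the threshold.
#' @export
confusion_metrics <- function(pred, mask, threshold = 0.5, fov = NULL) {
  if (!all(dim(pred) == dim(mask))) stop("pred and mask shapes differ")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (!is_binary(mask)) stop("mask must be binary (0/1)")
  keep <- if (is.null(fov)) rep(TRUE, length(mask)) else as.logical(fov != 0)
  if (!any(keep)) stop("evaluation region is empty")
  p <- as.numeric(pred)[keep] >= threshold
  y <- as.numeric(mask)[keep] == 1
  tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y); tn <- sum(!p & !y)
  rat <- function(a, b, what) {
    if (b == 0) { warning(what, " undefined: empty denominator"); return(NaN) }
    a / b
  }
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              se = rat(tp, tp + fn, "sensitivity"),
              sp = rat(tn, tn + fp, "specificity"),
              acc = (tp + tn) / (tp + tn + fp + fn),
              f1 = rat(2 * tp, 2 * tp + fp + fn, "F1"),
              threshold = threshold)
  class(out) <- "agc_metrics"
  out
}

#' @export
print.agc_metrics <- function(x, ...) {
  cat(sprintf("pixel metrics @ threshold %.2f\n", x$threshold))
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  SE %.4f  SP %.4f  ACC %.4f  F1 %.4f\n",
              x$se, x$sp, x$acc, x$f1))
  if (!is.null(x$auc)) cat(sprintf("  AUC %.4f\n", x$auc))
  invisible(x)
}

#' ROC curve and AUC of a probability map
#'
#' The ROC curve sweeps the decision threshold over every distinct predicted
#' value; the AUC is computed by the rank (Mann-Whitney) formula, i.e. the
#' probability that a random vessel pixel scores above a random background
#' pixel, ties counted half.
#'
#' @param pred probability map.
#' @param mask binary ground-truth mask containing both classes (within the
#'   FOV if given).
#' @param fov optional binary field-of-view mask.
#' @return list with `curve` (data.frame of `fpr`, `tpr`, threshold-sorted)
#'   and `auc`.
#' @export
roc_auc <- function(pred, mask, fov = NULL) {
  if (!all(dim(pred) == dim(mask))) stop("pred and mask shapes differ")
  keep <- if (is.null(fov)) rep(TRUE, length(mask)) else as.logical(fov != 0)
  p <- as.numeric(pred)[keep]
  y <- as.numeric(mask)[keep]
  if (!is_binary(y)) stop("mask must be binary (0/1)")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs both classes in the evaluation region")
  rk <- rank(p, ties.method = "average")
  auc <- (sum(rk[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # Curve: thresholds at each distinct score, descending.
  o <- order(p, decreasing = TRUE)
  ys <- y[o]; ps <- p[o]
  ctp <- cumsum(ys); cfp <- cumsum(1 - ys)
  last <- c(ps[-1] != ps[-length(ps)], TRUE)   # last index of each tie group
  curve <- data.frame(fpr = c(0, cfp[last] / n_neg),
                      tpr = c(0, ctp[last] / n_pos))
  list(curve = curve, auc = auc)
}

#' Plot a ROC curve to a PNG file
#'
#' @param roc result of [roc_auc()], or a named list of them for overlays.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_roc <- function(roc, path) {
  rocs <- if (!is.null(roc$curve)) list(model = roc) else roc
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "false positive rate",
       ylab = "true positive rate", main = "ROC")
  graphics::abline(0, 1, lty = 3, col = "grey")
  cols <- seq_along(rocs) + 1L
  for (i in seq_along(rocs))
    graphics::lines(rocs[[i]]$curve$fpr, rocs[[i]]$curve$tpr, col = cols[i],
                    lwd = 2)
  graphics::legend("bottomright", bty = "n", col = cols, lwd = 2,
                   legend = sprintf("%s (AUC %.4f)", names(rocs),
                                    vapply(rocs, function(r) r$auc, 0)))
  invisible(path)
}

# Pool per-image prediction/mask pairs into one flat pair (dataset-level
# metrics aggregate pixel counts before forming ratios).
pool_pixels <- function(preds, masks, fovs = NULL) {
  keep_one <- function(i) {
    f <- if (is.null(fovs) || is.null(fovs[[i]])) rep(TRUE, length(masks[[i]]))
         else as.logical(fovs[[i]] != 0)
    list(p = as.numeric(preds[[i]])[f], y = as.numeric(masks[[i]])[f])
  }
  parts <- lapply(seq_along(preds), keep_one)
  list(pred = unlist(lapply(parts, `[[`, "p")),
       mask = unlist(lapply(parts, `[[`, "y")))
}
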