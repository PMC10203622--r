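# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation: nested loops and direct
# formula transcription only.

# Direct convolution by quadruple loop (any stride/pad/dilation).
oracle_conv <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  K <- dim(w)[1]; Cout <- dim(w)[4]
  OH <- (H + 2 * pad - (dil * (K - 1) + 1)) %/% stride + 1
  OW <- (W + 2 * pad - (dil * (K - 1) + 1)) %/% stride + 1
  out <- array(0, c(OH, OW, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (oh in 1:OH) for (ow in 1:OW) {
    acc <- if (is.null(b)) 0 else b[co]
    for (ci in 1:Cin) for (kh in 1:K) for (kw in 1:K) {
      ih <- (oh - 1) * stride - pad + (kh - 1) * dil + 1
      iw <- (ow - 1) * stride - pad + (kw - 1) * dil + 1
      if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
        acc <- acc + x[ih, iw, ci, n] * w[kh, kw, ci, co]
    }
    out[oh, ow, co, n] <- acc
  }
  out
}

# Loss-weight map by two nested loops, transcribing the printed piecewise
# linear functions: vessel -num*0.04 + 2, background num*0.04 + 1, counting
# vessel pixels in the (2r+1)^2 box with zero outside the image.
oracle_pib_weights <- function(mask, r = 2) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    num <- 0
    for (p in (i - r):(i + r)) for (q in (j - r):(j + r))
      if (p >= 1 && p <= H && q >= 1 && q <= W) num <- num + mask[p, q]
    out[i, j] <- if (mask[i, j] == 1) -num * 0.04 + 2 else num * 0.04 + 1
  }
  out
}

# Plain per-pixel binary cross-entropy by explicit loop.
oracle_bce <- function(pred, mask, eps = 1e-7) {
  tot <- 0
  for (i in seq_along(pred)) {
    p <- min(max(pred[i], eps), 1 - eps)
    tot <- tot + if (mask[i] == 1) -log(p) else -log(1 - p)
  }
  tot / length(pred)
}

# AUC by O(n^2) pairwise comparison over all (positive, negative) pairs,
# ties counted one half.
oracle_auc <- function(pred, mask) {
  p <- as.numeric(pred); y <- as.numeric(mask)
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Largest 8-connected component extent (bounding-box side) of a binary mask.
component_extent <- function(m) {
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W); best <- 0
  for (start in which(m == 1)) {
    if (seen[start]) next
    q <- start; seen[start] <- TRUE; cells <- integer(0)
    while (length(q)) {
      cur <- q[1]; q <- q[-1]; cells <- c(cells, cur)
      y <- (cur - 1) %% H + 1; x <- (cur - 1) %/% H + 1
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W) {
          j <- (xx - 1) * H + yy
          if (m[j] == 1 && !seen[j]) { seen[j] <- TRUE; q <- c(q, j) }
        }
      }
    }
    ys <- (cells - 1) %% H + 1; xs <- (cells - 1) %/% H + 1
    best <- max(best, max(ys) - min(ys) + 1, max(xs) - min(xs) + 1)
  }
  best
}

# Small deterministic synthetic dataset for training tests.
tiny_data <- function(n_train, n_test, seed = 11) {
  generate_dataset(synthetic_spec(seed = seed), n_train, n_test)
}
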