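# Internal helpers: local RNG scoping and 4-D tensor bookkeeping.
# Tensor convention throughout the network code: numeric array (H, W, C, N).

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG to a given seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so generators never disturb global
#' reproducibility. All package randomness flows through this.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based child-seed derivation: deterministic, collision-poor within a
# run, and always a valid 32-bit integer.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + as.double(counter) * 104729 + 1) %%
               2147483647)
}

# Coerce a 2-D (H,W) or 3-D (H,W,C) array to the canonical 4-D (H,W,C,N).
as_t4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a vector")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 2-D, 3-D or 4-D array")
  x
}

# Drop trailing singleton dims of a 4-D tensor back to (H,W) or (H,W,C).
drop_t4 <- function(x) {
  d <- dim(x)
  if (d[4] == 1L && d[3] == 1L) dim(x) <- d[1:2]
  else if (d[4] == 1L) dim(x) <- d[1:3]
  x
}

zeros_like <- function(x) array(0, dim(x))

# Channel concatenation of 4-D tensors.
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(x, n_first) {
  d <- dim(x)
  list(first = x[, , seq_len(n_first), , drop = FALSE],
       rest  = x[, , n_first + seq_len(d[3] - n_first), , drop = FALSE])
}

clamp01 <- function(x, eps = 1e-7) pmin(pmax(x, eps), 1 - eps)

is_binary <- function(m) all(m %in% c(0, 1))
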