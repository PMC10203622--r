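# Deterministic synthetic fundus generator. Emulates the statistical
# structure the segmentation method targets: curvilinear vessel trees of
# mixed widths on a textured background, thin branches at reduced contrast,
# an over-bright disc region overlapping a vessel, an inscribed circular
# field of view, and a strongly imbalanced vessel:background pixel ratio.
# Not photorealistic; no pathology.

#' Specification of a synthetic fundus sample
#'
#' @param height,width image size in pixels; both must be divisible by 4
#'   (the network downsamples twice).
#' @param n_trees number of vessel trees (0 gives a background-only sample).
#' @param thick_width_range range (pixels) of trunk stroke widths.
#' @param thin_width_range range (pixels) of thin-branch widths; thin
#'   branches are drawn at reduced contrast.
#' @param thin_contrast_factor contrast of thin branches relative to trunks,
#'   in (0, 1].
#' @param disc_brightness peak added brightness of the over-bright disc
#'   region (>= 0).
#' @param noise_sd standard deviation of the additive intensity noise.
#' @param seed integer seed; all randomness is derived from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(height = 64L, width = 64L, n_trees = 3L,
                           thick_width_range = c(2, 4.5),
                           thin_width_range = c(1, 2),
                           thin_contrast_factor = 0.4,
                           disc_brightness = 0.35, noise_sd = 0.05,
                           seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_trees = as.integer(n_trees),
               thick_width_range = as.numeric(thick_width_range),
               thin_width_range = as.numeric(thin_width_range),
               thin_contrast_factor = as.numeric(thin_contrast_factor),
               disc_brightness = as.numeric(disc_brightness),
               noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (spec$height <= 0L || spec$width <= 0L)
    stop("height and width must be positive")
  if (spec$height %% 4L != 0L || spec$width %% 4L != 0L)
    stop("height and width must be divisible by 4")
  if (spec$n_trees < 0L) stop("n_trees must be >= 0")
  if (any(spec$thick_width_range < 1) || any(spec$thin_width_range < 1))
    stop("stroke widths must be >= 1 pixel")
  if (spec$thin_contrast_factor <= 0 || spec$thin_contrast_factor > 1)
    stop("thin_contrast_factor must be in (0, 1]")
  if (spec$disc_brightness < 0 || spec$noise_sd < 0)
    stop("disc_brightness and noise_sd must be >= 0")
  class(spec) <- "synthetic_spec"
  spec
}

# Separable bilinear resize of a matrix (used for the background texture).
resize_bilinear <- function(m, H, W) {
  src <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pmin(pmax(s, 0), n_in - 1)
  }
  sy <- src(H, nrow(m)); sx <- src(W, ncol(m))
  y0 <- pmin(floor(sy) + 1, nrow(m)); y1 <- pmin(y0 + 1, nrow(m))
  x0 <- pmin(floor(sx) + 1, ncol(m)); x1 <- pmin(x0 + 1, ncol(m))
  fy <- sy - (y0 - 1); fx <- sx - (x0 - 1)
  rows <- m[y0, , drop = FALSE] * (1 - fy) + m[y1, , drop = FALSE] * fy
  t(t(rows[, x0, drop = FALSE]) * (1 - fx) +
      t(rows[, x1, drop = FALSE]) * fx)
}

# One random-walk vessel tree: returns a data.frame of centreline points
# (x, y, width, contrast). Trunks may spawn narrower child branches; at
# least one thin, low-contrast branch is forced per tree.
grow_tree <- function(spec, force_span = FALSE) {
  H <- spec$height; W <- spec$width
  pts <- list()
  walkers <- list()
  if (force_span) {
    # Trunk crossing the image left-to-right: guarantees a connected
    # component of extent >= H/2.
    walkers[[1]] <- list(x = 1, y = runif(1, 0.3, 0.7) * H,
                         angle = runif(1, -0.15, 0.15),
                         w = runif(1, spec$thick_width_range[1],
                                   spec$thick_width_range[2]),
                         contrast = 1, steps = ceiling(2.5 * W))
  } else {
    side <- sample(4L, 1L)
    start <- switch(side,
                    list(x = 1, y = runif(1) * H, a = 0),
                    list(x = W, y = runif(1) * H, a = pi),
                    list(x = runif(1) * W, y = 1, a = pi / 2),
                    list(x = runif(1) * W, y = H, a = -pi / 2))
    walkers[[1]] <- list(x = start$x, y = start$y,
                         angle = start$a + runif(1, -0.3, 0.3),
                         w = runif(1, spec$thick_width_range[1],
                                   spec$thick_width_range[2]),
                         contrast = 1, steps = ceiling(1.2 * max(H, W)))
  }
  trunk_pts <- NULL
  k <- 0L
  while (length(walkers) > 0L && k < 40L) {
    wk <- walkers[[1]]; walkers[[1]] <- NULL
    k <- k + 1L
    step <- 0.6
    trace <- matrix(0, wk$steps, 2)
    n_used <- 0L
    for (s in seq_len(wk$steps)) {
      wk$x <- wk$x + step * cos(wk$angle)
      wk$y <- wk$y + step * sin(wk$angle)
      if (wk$x < -2 || wk$x > W + 2 || wk$y < -2 || wk$y > H + 2) break
      wk$angle <- wk$angle + rnorm(1, 0, 0.10)
      wk$w <- max(wk$w * 0.9985, 1)
      n_used <- n_used + 1L
      trace[n_used, ] <- c(wk$x, wk$y)
      pts[[length(pts) + 1L]] <- c(wk$x, wk$y, wk$w, wk$contrast)
      if (runif(1) < 0.015 && length(walkers) + k < 10L) {
        walkers[[length(walkers) + 1L]] <-
          list(x = wk$x, y = wk$y,
               angle = wk$angle + sample(c(-1, 1), 1) * runif(1, 0.4, 1.0),
               w = max(wk$w * 0.65, 1),
               contrast = if (wk$w * 0.65 <= max(spec$thin_width_range))
                 spec$thin_contrast_factor else wk$contrast,
               steps = ceiling(wk$steps / 2))
      }
    }
    if (k == 1L && n_used > 2L) trunk_pts <- trace[seq_len(n_used), , drop = FALSE]
    # Forced thin low-contrast branch off the trunk.
    if (k == 1L && n_used > 4L) {
      at <- trunk_pts[sample(n_used, 1L), ]
      walkers[[length(walkers) + 1L]] <-
        list(x = at[1], y = at[2],
             angle = runif(1, 0, 2 * pi),
             w = runif(1, spec$thin_width_range[1], spec$thin_width_range[2]),
             contrast = spec$thin_contrast_factor,
             steps = ceiling(0.6 * max(H, W)))
    }
  }
  list(points = do.call(rbind, pts), trunk = trunk_pts)
}

# Stamp centreline points as discs into a (shared) mask and darkness map.
# Stamping stops once the vessel pixel count reaches `budget`, which keeps
# every sample inside the strongly imbalanced minority-class regime the
# weighted loss is designed for.
stamp_points <- function(pts, mask, dark, budget) {
  if (is.null(pts) || nrow(pts) == 0L) return(list(mask = mask, dark = dark))
  H <- nrow(mask); W <- ncol(mask)
  offsets_for <- function(r) {
    q <- ceiling(r)
    g <- expand.grid(dy = -q:q, dx = -q:q)
    g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  }
  radii <- pmax(pts[, 3] / 2, 0.6)
  keys <- round(radii, 1)
  off_cache <- lapply(unique(keys), offsets_for)
  names(off_cache) <- as.character(unique(keys))
  n_on <- sum(mask)
  for (i in seq_len(nrow(pts))) {
    if (n_on >= budget) break
    off <- off_cache[[as.character(keys[i])]]
    iy <- round(pts[i, 2]) + off$dy
    ix <- round(pts[i, 1]) + off$dx
    ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
    if (!any(ok)) next
    idx <- cbind(iy[ok], ix[ok])
    n_on <- n_on + sum(mask[idx] == 0)
    mask[idx] <- 1
    dark[idx] <- pmax(dark[idx], pts[i, 4])
  }
  list(mask = mask, dark = dark)
}

#' Generate one synthetic fundus sample
#'
#' Deterministic in `spec$seed`: the same spec always yields bit-identical
#' output. The image is a textured warm-toned background with vessel trees
#' drawn darker than the background (thin branches at reduced contrast), an
#' over-bright disc region placed on the first tree's trunk, and additive
#' noise; intensities are clipped to `[0, 1]`.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `fundus_sample`: list with `image` (H x W x 3,
#'   in `[0,1]`), `mask` (H x W binary), `fov` (H x W binary inscribed
#'   circle).
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$height; W <- spec$width
  with_seed(spec$seed, {
    base <- c(0.66, 0.40, 0.22)
    chan_tex <- c(1.0, 0.9, 0.7)
    tex <- resize_bilinear(matrix(rnorm(81, 0, 0.05), 9, 9), H, W)
    mask <- matrix(0, H, W)
    dark <- matrix(0, H, W)
    disc_centre <- NULL
    if (spec$n_trees > 0L) {
      budget <- floor(0.24 * H * W)
      for (t in seq_len(spec$n_trees)) {
        tree <- grow_tree(spec, force_span = (t == 1L))
        st <- stamp_points(tree$points, mask, dark, budget)
        mask <- st$mask
        dark <- st$dark
        if (t == 1L && !is.null(tree$trunk))
          disc_centre <- tree$trunk[sample(nrow(tree$trunk), 1L), ]
      }
    }
    disc <- matrix(0, H, W)
    if (!is.null(disc_centre) && spec$disc_brightness > 0) {
      r <- min(H, W) / 7
      yy <- matrix(seq_len(H), H, W)
      xx <- matrix(seq_len(W), H, W, byrow = TRUE)
      d2 <- (yy - disc_centre[2])^2 + (xx - disc_centre[1])^2
      disc <- spec$disc_brightness * exp(-d2 / (2 * (r / 1.5)^2))
    }
    img <- array(0, c(H, W, 3))
    depth <- 0.35 * c(1.0, 1.0, 0.8)
    for (cc in 1:3)
      img[, , cc] <- base[cc] + chan_tex[cc] * tex - depth[cc] * dark + disc
    img <- img + array(rnorm(H * W * 3, 0, spec$noise_sd), c(H, W, 3))
    img <- pmin(pmax(img, 0), 1)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    fov <- ((yy - (H + 1) / 2)^2 + (xx - (W + 1) / 2)^2 <=
              (min(H, W) / 2)^2) * 1
    structure(list(image = img, mask = mask, fov = fov, spec = spec),
              class = "fundus_sample")
  })
}

#' Generate a train/test dataset of synthetic samples
#'
#' Each sample uses its own seed derived deterministically from `spec$seed`
#' and its position (counter-based), so train and test sets are disjoint by
#' construction and the whole dataset is reproducible.
#'
#' @param spec a [synthetic_spec()] (its `seed` is the master seed).
#' @param n_train,n_test sample counts (>= 0).
#' @return list with `train` and `test`, each a list of `fundus_sample`.
#' @export
generate_dataset <- function(spec, n_train, n_test) {
  stopifnot(n_train >= 0, n_test >= 0)
  gen <- function(counter) {
    s <- spec
    s$seed <- derive_seed(spec$seed, counter)
    generate_sample(s)
  }
  list(train = lapply(seq_len(n_train), gen),
       test = lapply(n_train + seq_len(n_test), gen))
}

#' Write samples to a flat directory layout
#'
#' Writes `img_XXX.png`, `mask_XXX.png` and `fov_XXX.png` triples, the
#' layout [load_dataset()] reads back with `layout = "flat"`.
#'
#' @param samples list of `fundus_sample`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_samples <- function(samples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    png::writePNG(s$image, file.path(dir, sprintf("img_%03d.png", i)))
    png::writePNG(s$mask, file.path(dir, sprintf("mask_%03d.png", i)))
    if (!is.null(s$fov))
      png::writePNG(s$fov, file.path(dir, sprintf("fov_%03d.png", i)))
  }
  invisible(dir)
}
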