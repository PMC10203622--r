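# Reading image/mask/FOV triples (DRIVE-, CHASE- and flat-layout), the
# zero-pad / crop-back convention, and training-time augmentation.

#' Padding specification
#'
#' Records target size, original size and placement offsets so that
#' [crop_back()] exactly inverts [pad_to()]. Padding is centred: the
#' original content sits at `offsets` (top, left), the remainder pixel going
#' to the bottom/right.
#'
#' @param original_height,original_width input size in pixels.
#' @param target_height,target_width padded size; must be >= original.
#' @return an `agc_padspec` list with fields `target`, `original`, `offsets`.
#' @export
pad_spec <- function(original_height, original_width,
                     target_height, target_width) {
  if (target_height < original_height || target_width < original_width)
    stop("target size must be at least the original size")
  structure(list(target = c(as.integer(target_height),
                            as.integer(target_width)),
                 original = c(as.integer(original_height),
                              as.integer(original_width)),
                 offsets = c(top = (target_height - original_height) %/% 2L,
                             left = (target_width - original_width) %/% 2L)),
            class = "agc_padspec")
}

#' Automatic padding target for a given image size
#'
#' Pads to the smallest square whose side is a multiple of 16 and covers
#' both dimensions -- the convention that maps 584 x 565 to 592 x 592 and
#' 999 x 960 to 1008 x 1008 (and leaves already-conforming sizes alone).
#'
#' @param height,width original size.
#' @param multiple side-length granularity (default 16).
#' @return an `agc_padspec`.
#' @export
pad_spec_auto <- function(height, width, multiple = 16L) {
  side <- as.integer(multiple * ceiling(max(height, width) / multiple))
  pad_spec(height, width, side, side)
}

#' Zero-pad an image or mask to a target size
#'
#' @param x 2-D (H, W) or 3-D (H, W, C) array matching `pad$original`.
#' @param pad an [pad_spec()].
#' @return array of target size; original content at the recorded offsets,
#'   new pixels zero.
#' @export
pad_to <- function(x, pad) {
  stopifnot(inherits(pad, "agc_padspec"))
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% 2:3)) stop("expected a 2-D or 3-D array")
  if (d[1] != pad$original[1] || d[2] != pad$original[2])
    stop("input size ", d[1], "x", d[2], " does not match pad$original ",
         pad$original[1], "x", pad$original[2])
  C <- if (length(d) == 3L) d[3] else 1L
  out <- array(0, c(pad$target, C))
  out[pad$offsets[1] + seq_len(d[1]), pad$offsets[2] + seq_len(d[2]), ] <-
    array(x, c(d[1], d[2], C))
  if (length(d) == 2L) dim(out) <- pad$target
  out
}

#' Crop a padded array back to its original size
#'
#' Exact inverse of [pad_to()]: `crop_back(pad_to(x, p), p)` is identical to
#' `x` for every input.
#'
#' @param padded array at `pad$target` size (2-D or 3-D).
#' @param pad an [pad_spec()].
#' @return array at `pad$original` size.
#' @export
crop_back <- function(padded, pad) {
  stopifnot(inherits(pad, "agc_padspec"))
  d <- dim(padded)
  if (d[1] != pad$target[1] || d[2] != pad$target[2])
    stop("padded size ", d[1], "x", d[2], " does not match pad$target ",
         pad$target[1], "x", pad$target[2])
  rows <- pad$offsets[1] + seq_len(pad$original[1])
  cols <- pad$offsets[2] + seq_len(pad$original[2])
  if (length(d) == 3L) padded[rows, cols, , drop = FALSE]
  else padded[rows, cols, drop = FALSE]
}

#' Augmentation specification
#'
#' @param hflip_prob,vflip_prob probabilities of horizontal / vertical flips.
#' @param rotation_range rotation is drawn uniformly from
#'   `[-rotation_range, rotation_range]` degrees (bilinear for the image,
#'   nearest-neighbour for mask and FOV, so masks stay binary).
#' @param jitter_brightness,jitter_contrast,jitter_saturation colour-jitter
#'   factors: each multiplier is drawn from `[1 - f, 1 + f]`; applied to the
#'   image only.
#' @param seed integer seed.
#' @return an `augment_spec` list.
#' @export
augment_spec <- function(hflip_prob = 0.5, vflip_prob = 0.5,
                         rotation_range = 180, jitter_brightness = 0.2,
                         jitter_contrast = 0.2, jitter_saturation = 0.2,
                         seed = 1L) {
  if (hflip_prob < 0 || hflip_prob > 1 || vflip_prob < 0 || vflip_prob > 1)
    stop("flip probabilities must be in [0, 1]")
  if (rotation_range < 0) stop("rotation_range must be >= 0")
  structure(list(hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 rotation_range = rotation_range,
                 jitter_brightness = jitter_brightness,
                 jitter_contrast = jitter_contrast,
                 jitter_saturation = jitter_saturation,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

# Sample a matrix at arbitrary (row, col) coordinates. Bilinear or nearest;
# coordinates outside the matrix return `fill`.
sample_at <- function(m, ys, xs, method = c("bilinear", "nearest"),
                      fill = 0) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  out <- rep(fill, length(ys))
  if (method == "nearest") {
    iy <- round(ys); ix <- round(xs)
    ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
    out[ok] <- m[cbind(iy[ok], ix[ok])]
  } else {
    ok <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    y0 <- pmin(floor(ys[ok]), H - 1); x0 <- pmin(floor(xs[ok]), W - 1)
    fy <- ys[ok] - y0; fx <- xs[ok] - x0
    v <- m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
      m[cbind(y0 + 1, x0)] * fy * (1 - fx) +
      m[cbind(y0, x0 + 1)] * (1 - fy) * fx +
      m[cbind(y0 + 1, x0 + 1)] * fy * fx
    out[ok] <- v
  }
  out
}

rotate_plane <- function(m, angle_deg, method, fill = 0) {
  if (angle_deg == 0) return(m)
  H <- nrow(m); W <- ncol(m)
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse mapping: rotate output coordinates by -angle
  sy <- cy + (cos(th) * yy + sin(th) * xx)
  sx <- cx + (-sin(th) * yy + cos(th) * xx)
  matrix(sample_at(m, as.numeric(sy), as.numeric(sx), method, fill), H, W)
}

#' Augment a sample (geometric + colour jitter)
#'
#' Image, mask and FOV receive identical geometric transforms (flips and a
#' random rotation); the mask and FOV are resampled nearest-neighbour so
#' they stay binary, the image bilinearly. Colour jitter (brightness,
#' contrast, saturation) is applied to the image only. Deterministic in
#' `seed`.
#'
#' @param sample a `fundus_sample` (or any list with `image`, `mask`,
#'   optional `fov`).
#' @param spec an [augment_spec()].
#' @param seed seed for this draw; defaults to `spec$seed`.
#' @return the augmented sample.
#' @export
augment <- function(sample, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "augment_spec"))
  with_seed(seed, {
    img <- sample$image; mask <- sample$mask; fov <- sample$fov
    if (runif(1) < spec$hflip_prob) {
      img <- img[, rev(seq_len(ncol(mask))), , drop = FALSE]
      mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
      if (!is.null(fov)) fov <- fov[, rev(seq_len(ncol(fov))), drop = FALSE]
    }
    if (runif(1) < spec$vflip_prob) {
      img <- img[rev(seq_len(nrow(mask))), , , drop = FALSE]
      mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
      if (!is.null(fov)) fov <- fov[rev(seq_len(nrow(fov))), , drop = FALSE]
    }
    if (spec$rotation_range > 0) {
      ang <- runif(1, -spec$rotation_range, spec$rotation_range)
      for (cc in seq_len(dim(img)[3]))
        img[, , cc] <- rotate_plane(img[, , cc], ang, "bilinear")
      mask <- rotate_plane(mask, ang, "nearest")
      if (!is.null(fov)) fov <- rotate_plane(fov, ang, "nearest")
    }
    if (spec$jitter_brightness > 0)
      img <- img * runif(1, 1 - spec$jitter_brightness,
                         1 + spec$jitter_brightness)
    if (spec$jitter_contrast > 0) {
      f <- runif(1, 1 - spec$jitter_contrast, 1 + spec$jitter_contrast)
      img <- (img - mean(img)) * f + mean(img)
    }
    if (spec$jitter_saturation > 0) {
      f <- runif(1, 1 - spec$jitter_saturation, 1 + spec$jitter_saturation)
      gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
      for (cc in 1:3) img[, , cc] <- gray + (img[, , cc] - gray) * f
    }
    img <- pmin(pmax(img, 0), 1)
    out <- sample
    out$image <- img; out$mask <- mask; out$fov <- fov
    out
  })
}

# ---- raster reading -------------------------------------------------------

# PNG and TIFF natively; anything else through EBImage when available.
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading '", ext, "' requires the 'EBImage' package")
    img <- EBImage::readImage(path)
    a <- as.array(img)
    if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
  }
  x
}

read_image_rgb <- function(path) {
  x <- read_raster(path)
  d <- dim(x)
  if (length(d) == 2L) {
    x <- array(rep(x, 3L), c(d, 3L))
  } else if (d[3] == 2L) {                        # gray + alpha
    x <- array(rep(x[, , 1], 3L), c(d[1], d[2], 3L))
  } else if (d[3] > 3L) {                         # drop alpha
    x <- x[, , 1:3, drop = FALSE]
  }
  pmin(pmax(x, 0), 1)
}

# Annotations are near-binary rasters; threshold at half range so
# antialiased PNGs load as clean 0/1 masks.
read_mask_binary <- function(path) {
  x <- read_raster(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x > 0.5) * 1
}

list_stems <- function(dir, pattern) {
  f <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  f
}

find_for_stem <- function(dir, stem_regex, what) {
  f <- sort(list.files(dir, pattern = stem_regex, full.names = TRUE))
  if (length(f) == 0L)
    stop("missing ", what, " matching '", stem_regex, "' in ", dir)
  f[1]
}

#' Load a dataset in DRIVE, CHASE_DB1 or flat layout
#'
#' * `"flat"`: one directory of `img_*.{png,tif}` with matching `mask_*` and
#'   optional `fov_*` files (the layout [write_samples()] writes). All
#'   samples are returned in `$train`; split as you see fit.
#' * `"drive"`: `training/` and `test/` subdirectories, each with `images/`,
#'   `1st_manual/` and `mask/` (FOV); the official 20/20 split is the
#'   directory structure itself.
#' * `"chase"`: one directory of `Image_*.jpg|png` with `*_1stHO.png` /
#'   `*_2ndHO.png` annotations; samples are sorted by filename, the first 20
#'   become training and the remainder (8 for the full set) test.
#'
#' Loading order is lexicographic in every layout, so it is deterministic.
#' A missing annotation raises an error naming the image stem.
#'
#' @param root dataset directory.
#' @param layout one of `"flat"`, `"drive"`, `"chase"`.
#' @param annotator for CHASE, which manual annotation to use (1 or 2).
#' @return list with `train` and `test` lists of `fundus_sample`.
#' @export
load_dataset <- function(root, layout = c("flat", "drive", "chase"),
                         annotator = 1L) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stop("no such directory: ", root)
  if (layout == "flat") {
    imgs <- list_stems(root, "^img_.*\\.(png|tif|tiff)$")
    if (length(imgs) == 0L) stop("no img_* files found in ", root)
    samples <- lapply(imgs, function(f) {
      stem <- sub("^img_", "", sub("\\.[^.]+$", "", basename(f)))
      maskf <- file.path(root, paste0("mask_", stem, ".png"))
      if (!file.exists(maskf))
        stop("missing mask for stem '", stem, "': expected ", maskf)
      fovf <- file.path(root, paste0("fov_", stem, ".png"))
      structure(list(image = read_image_rgb(f),
                     mask = read_mask_binary(maskf),
                     fov = if (file.exists(fovf)) read_mask_binary(fovf)
                           else NULL),
                class = "fundus_sample")
    })
    return(list(train = samples, test = list()))
  }
  if (layout == "drive") {
    load_split <- function(sub) {
      imgs <- list_stems(file.path(root, sub, "images"), "\\.(png|tif|tiff|gif|jpg)$")
      lapply(imgs, function(f) {
        stem <- sub("_.*$", "", basename(f))   # e.g. "21" from 21_training.tif
        manf <- find_for_stem(file.path(root, sub, "1st_manual"),
                              paste0("^", stem, "_"), "manual annotation")
        fovd <- file.path(root, sub, "mask")
        fovf <- if (dir.exists(fovd))
          tryCatch(find_for_stem(fovd, paste0("^", stem, "_"), "fov"),
                   error = function(e) NULL) else NULL
        structure(list(image = read_image_rgb(f),
                       mask = read_mask_binary(manf),
                       fov = if (!is.null(fovf)) read_mask_binary(fovf)
                             else NULL),
                  class = "fundus_sample")
      })
    }
    return(list(train = load_split("training"), test = load_split("test")))
  }
  # CHASE: stems sorted lexicographically, first 20 train, rest test.
  imgs <- list_stems(root, "^Image_[0-9]+[LR]\\.(jpg|png|tif|tiff)$")
  if (length(imgs) == 0L) stop("no Image_* files found in ", root)
  suffix <- if (annotator == 1L) "_1stHO" else "_2ndHO"
  samples <- lapply(imgs, function(f) {
    stem <- sub("\\.[^.]+$", "", basename(f))
    annf <- list.files(root, pattern = paste0("^", stem, suffix,
                                              "\\.(png|tif|tiff|gif)$"),
                       full.names = TRUE)
    if (length(annf) == 0L)
      stop("missing annotation for stem '", stem, "' (", suffix, ")")
    structure(list(image = read_image_rgb(f),
                   mask = read_mask_binary(annf[1]), fov = NULL),
              class = "fundus_sample")
  })
  n_train <- min(20L, length(samples))
  list(train = samples[seq_len(n_train)],
       test = if (length(samples) > n_train)
         samples[(n_train + 1L):length(samples)] else list())
}
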