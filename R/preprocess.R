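#' Patch preprocessing configuration
#'
#' Controls the tile-to-tensor pipeline: optional training-time augmentation
#' (random horizontal flip and a mild random affine transform keeping the tile
#' centre invariant), optional integer downsampling emulating lower
#' magnification, a centre crop, and per-channel z-score normalisation with
#' dataset-level statistics.
#'
#' @param crop_size Output edge in pixels (224 for 512 tiles at 20x; smaller
#'   for synthetic tiles).
#' @param channel_mean,channel_std Length-3 RGB statistics computed once over
#'   the retained training patches; `channel_std` must be strictly positive.
#' @param augment Apply the random flip/affine augmentation (training only).
#' @param magnification_factor Integer downsample factor 1, 2 or 4 emulating
#'   20x / 10x / 5x input.
#' @param rotation_deg,shear_deg,scale_range Augmentation ranges (degrees,
#'   degrees, multiplicative span); mild by design, centre fixed.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(crop_size = 224L,
                              channel_mean = c(0.5, 0.5, 0.5),
                              channel_std = c(0.25, 0.25, 0.25),
                              augment = FALSE,
                              magnification_factor = 1L,
                              rotation_deg = 10, shear_deg = 5,
                              scale_range = c(0.9, 1.1)) {
  stopifnot(length(channel_mean) == 3, length(channel_std) == 3)
  if (any(channel_std <= 0)) stop_pathomsi("channel_std must be strictly positive")
  if (!magnification_factor %in% c(1L, 2L, 4L)) {
    stop_pathomsi("magnification_factor must be 1, 2 or 4")
  }
  structure(list(crop_size = as.integer(crop_size),
                 channel_mean = channel_mean, channel_std = channel_std,
                 augment = isTRUE(augment),
                 magnification_factor = as.integer(magnification_factor),
                 rotation_deg = rotation_deg, shear_deg = shear_deg,
                 scale_range = scale_range),
            class = "preprocess_config")
}

# Bilinear affine warp about the image centre; edge-clamped sampling.
affine_warp <- function(img, mat) {
  h <- dim(img)[1]; w <- dim(img)[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  inv <- solve(mat)
  gy <- rep(seq_len(h), times = w) - cy
  gx <- rep(seq_len(w), each = h) - cx
  sx <- inv[1, 1] * gx + inv[1, 2] * gy + cx
  sy <- inv[2, 1] * gx + inv[2, 2] * gy + cy
  sx <- pmin(pmax(sx, 1), w); sy <- pmin(pmax(sy, 1), h)
  x0 <- floor(sx); y0 <- floor(sy)
  x1 <- pmin(x0 + 1, w); y1 <- pmin(y0 + 1, h)
  fx <- sx - x0; fy <- sy - y0
  out <- img
  for (c in seq_len(dim(img)[3])) {
    ch <- img[, , c]
    v <- (1 - fx) * (1 - fy) * ch[cbind(y0, x0)] +
      fx * (1 - fy) * ch[cbind(y0, x1)] +
      (1 - fx) * fy * ch[cbind(y1, x0)] +
      fx * fy * ch[cbind(y1, x1)]
    out[, , c] <- matrix(v, nrow = h, ncol = w)
  }
  out
}

# 2x2... block-mean downsample by integer factor.
block_downsample <- function(img, factor) {
  if (factor == 1L) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  stopifnot(h %% factor == 0, w %% factor == 0)
  out <- array(0, c(h / factor, w / factor, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) {
    m <- img[, , c]
    m <- matrix(colMeans(matrix(m, nrow = factor)), nrow = h / factor)
    m <- t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = w / factor))
    out[, , c] <- m
  }
  out
}

#' Preprocess one tile into a model input tensor
#'
#' Training-time augmentation (random horizontal flip, then a random affine
#' transform with rotation, shear and scale about the fixed tile centre) is
#' applied before the centre crop; the crop is followed by per-channel
#' z-score normalisation `(x - mean) / std` using the configured dataset
#' statistics. With a 512 tile and a 224 crop, output pixel (0,0) is input
#' pixel (144,144) (0-based).
#'
#' @param img `H x W x 3` numeric array, values in `[0, 1]`.
#' @param cfg A [preprocess_config()].
#' @return `crop_size x crop_size x 3` numeric array.
#' @export
preprocess_patch <- function(img, cfg = preprocess_config()) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) stop_pathomsi("patch must be an H x W x 3 array")
  if (cfg$augment) {
    if (runif(1) < 0.5) img <- img[, rev(seq_len(d[2])), , drop = FALSE]
    th <- runif(1, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
    sh <- tan(runif(1, -cfg$shear_deg, cfg$shear_deg) * pi / 180)
    sc <- runif(1, cfg$scale_range[1], cfg$scale_range[2])
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    shear <- matrix(c(1, 0, sh, 1), 2)
    img <- affine_warp(img, sc * rot %*% shear)
  }
  img <- block_downsample(img, cfg$magnification_factor)
  d <- dim(img)
  cs <- cfg$crop_size
  if (d[1] < cs || d[2] < cs) stop_pathomsi("patch smaller than crop_size after downsampling")
  off_y <- (d[1] - cs) %/% 2
  off_x <- (d[2] - cs) %/% 2
  img <- img[(off_y + 1):(off_y + cs), (off_x + 1):(off_x + cs), , drop = FALSE]
  for (c in 1:3) {
    img[, , c] <- (img[, , c] - cfg$channel_mean[c]) / cfg$channel_std[c]
  }
  img
}

# Dataset-level RGB channel statistics over a list of tiles.
channel_stats <- function(tiles) {
  ch <- vapply(1:3, function(c) {
    vals <- unlist(lapply(tiles, function(t) t[, , c]))
    c(mean(vals), sd(vals))
  }, numeric(2))
  list(mean = ch[1, ], std = pmax(ch[2, ], 1e-6))
}
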