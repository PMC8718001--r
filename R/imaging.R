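# Mask-driven cropping, contrast enhancement and training-time affine
# augmentation. Images are H x W matrices of intensities in [0, 1].
# Box coordinates are 0-based and half-open [start, end).

#' Tight bounding box of a binary mask
#'
#' @param mask binary `H x W` matrix with at least one foreground pixel.
#' @return list with `row_start`, `row_end`, `col_start`, `col_end`
#'   (0-based, half-open).
#' @export
mask_to_bbox <- function(mask) {
  check_binary_mask(mask)
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0L) {
    stop("mask has no foreground pixels; refusing to invent a box", call. = FALSE)
  }
  list(row_start = min(fg[, 1]) - 1L, row_end = max(fg[, 1]),
       col_start = min(fg[, 2]) - 1L, col_end = max(fg[, 2]))
}

# Catmull-Rom cubic kernel (a = -0.5), the classical bicubic weight.
.cubic_kernel <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# Dense 1-D bicubic resampling matrix mapping n_in samples to n_out, with
# pixel-center alignment and clamped borders.
.resample_matrix <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5          # 0-based source coordinate
    base <- floor(src)
    for (off in -1:2) {
      j <- base + off
      wgt <- .cubic_kernel(src - j)
      jc <- min(max(j, 0), n_in - 1)        # clamp at the borders
      W[i, jc + 1] <- W[i, jc + 1] + wgt
    }
  }
  W
}

#' Crop a box and resize with bicubic interpolation
#'
#' Crops the half-open box from the image and resamples it to
#' `size x size` pixels (or `size = c(h, w)`) using separable Catmull-Rom
#' bicubic interpolation with pixel-center alignment; values are clipped
#' back to `[0, 1]` (the cubic kernel can overshoot at edges).
#'
#' @param img `H x W` intensity matrix in `[0, 1]`.
#' @param box bounding box as from [mask_to_bbox()].
#' @param size output size: scalar side length or `c(height, width)`.
#' @return resized intensity matrix in `[0, 1]`.
#' @export
crop_resize <- function(img, box, size) {
  if (!is.matrix(img)) stop("img must be a matrix", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  with_box <- function(v) as.integer(v)
  rs <- with_box(box$row_start); re <- with_box(box$row_end)
  cs <- with_box(box$col_start); ce <- with_box(box$col_end)
  if (is.na(rs) || rs < 0L || re > h || cs < 0L || ce > w || rs >= re || cs >= ce) {
    stop("box must be non-degenerate and inside the image", call. = FALSE)
  }
  crop <- img[(rs + 1L):re, (cs + 1L):ce, drop = FALSE]
  size <- as.integer(if (length(size) == 1L) c(size, size) else size)
  if (any(size < 1L)) stop("output size must be positive", call. = FALSE)
  out <- .resample_matrix(nrow(crop), size[1]) %*% crop %*%
    t(.resample_matrix(ncol(crop), size[2]))
  pmin(pmax(out, 0), 1)
}

#' Percentile contrast stretch
#'
#' Saturates the bottom `low_pct` and top `high_pct` percent of all image
#' pixels and maps the remaining range linearly to `[0, 1]`. Percentiles
#' are computed over the whole image as empirical (inverse-ECDF) quantiles,
#' which makes the stretch exactly idempotent: re-applying it changes
#' nothing once the tails are saturated. A constant image returns all
#' zeros (documented convention).
#'
#' @param img `H x W` intensity matrix.
#' @param low_pct,high_pct saturated tail sizes in percent (default 1).
#' @return stretched image with min 0 and max 1 (unless constant input).
#' @export
contrast_stretch <- function(img, low_pct = 1, high_pct = 1) {
  if (!is.matrix(img) || length(img) == 0L) {
    stop("img must be a non-empty matrix", call. = FALSE)
  }
  lo <- stats::quantile(img, low_pct / 100, names = FALSE, type = 1)
  hi <- stats::quantile(img, 1 - high_pct / 100, names = FALSE, type = 1)
  if (hi <= lo) return(matrix(0, nrow(img), ncol(img)))
  pmin(pmax((img - lo) / (hi - lo), 0), 1)
}

#' Augmentation specification
#'
#' Ranges follow the training protocol: integer pixel shifts in
#' `[-max_shift_px, +max_shift_px]` (at most 2), optional horizontal
#' flipping, and rotations in `[-max_rotation_deg, +max_rotation_deg]`
#' degrees (at most 5).
#'
#' @param max_shift_px maximum absolute shift in pixels, in `[0, 2]`.
#' @param hflip allow horizontal flips?
#' @param max_rotation_deg maximum absolute rotation, in `[0, 5]` degrees.
#' @param seed integer RNG seed.
#' @return list of class `augment_spec`.
#' @export
augment_spec <- function(max_shift_px = 2, hflip = TRUE,
                         max_rotation_deg = 5, seed = 1) {
  if (max_shift_px < 0 || max_shift_px > 2) {
    stop("max_shift_px must lie in [0, 2]", call. = FALSE)
  }
  if (max_rotation_deg < 0 || max_rotation_deg > 5) {
    stop("max_rotation_deg must lie in [0, 5]", call. = FALSE)
  }
  structure(list(max_shift_px = as.integer(max_shift_px),
                 hflip = isTRUE(hflip),
                 max_rotation_deg = max_rotation_deg,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

# Inverse-map affine sampler. `interp` is "bilinear" (image) or
# "nearest" (mask); out-of-bounds samples are filled with 0.
.affine_sample <- function(img, dy, dx, flip, angle_rad, interp) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  # undo shift, then rotation about the center, then flip
  yr <- rr - dy - cy; xr <- cc - dx - cx
  ca <- cos(-angle_rad); sa <- sin(-angle_rad)
  ys <- ca * yr - sa * xr + cy
  xs <- sa * yr + ca * xr + cx
  if (flip) xs <- w + 1 - xs
  if (interp == "nearest") {
    yi <- round(ys); xi <- round(xs)
    ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
    out <- matrix(0, h, w)
    out[ok] <- img[cbind(yi[ok], xi[ok])]
    out
  } else {
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    gather <- function(yy, xx) {
      ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
      v <- matrix(0, h, w)
      v[ok] <- img[cbind(yy[ok], xx[ok])]
      v
    }
    gather(y0, x0) * (1 - fy) * (1 - fx) +
      gather(y0, x0 + 1) * (1 - fy) * fx +
      gather(y0 + 1, x0) * fy * (1 - fx) +
      gather(y0 + 1, x0 + 1) * fy * fx
  }
}

#' Random affine augmentation of an image/mask pair
#'
#' Draws one transform (integer pixel shift, optional horizontal flip,
#' small rotation) from the spec's ranges and applies the identical
#' transform to the image (bilinear interpolation) and its mask
#' (nearest-neighbour, re-binarized at 0.5, which avoids phantom
#' foreground). Uncovered border pixels are filled with 0. Deterministic
#' per `spec$seed`.
#'
#' @param img `H x W` intensity matrix.
#' @param mask binary `H x W` mask.
#' @param spec an [augment_spec()].
#' @return list with transformed `image` and `mask`, plus the drawn
#'   `transform` parameters.
#' @export
augment <- function(img, mask, spec) {
  if (!inherits(spec, "augment_spec")) {
    stop("spec must be an augment_spec()", call. = FALSE)
  }
  check_binary_mask(mask)
  check_same_shape(img, mask, "image and mask")
  draw <- with_seed(spec$seed, {
    list(
      dy = sample(seq(-spec$max_shift_px, spec$max_shift_px), 1L),
      dx = sample(seq(-spec$max_shift_px, spec$max_shift_px), 1L),
      flip = spec$hflip && stats::runif(1) < 0.5,
      angle = stats::runif(1, -spec$max_rotation_deg, spec$max_rotation_deg) * pi / 180
    )
  })
  img_t <- .affine_sample(img, draw$dy, draw$dx, draw$flip, draw$angle, "bilinear")
  mask_t <- .affine_sample(mask, draw$dy, draw$dx, draw$flip, draw$angle, "nearest")
  mask_t <- (mask_t >= 0.5) * 1
  list(image = pmin(pmax(img_t, 0), 1), mask = mask_t, transform = draw)
}

#' Apply a fixed affine transform to an image/mask pair
#'
#' Deterministic workhorse behind [augment()], exposed for composition
#' checks and custom pipelines.
#'
#' @inheritParams augment
#' @param dy,dx integer pixel shifts.
#' @param flip horizontal flip?
#' @param angle_deg rotation in degrees (about the image center).
#' @return list with transformed `image` and `mask`.
#' @export
apply_affine <- function(img, mask, dy = 0, dx = 0, flip = FALSE, angle_deg = 0) {
  check_binary_mask(mask)
  check_same_shape(img, mask, "image and mask")
  a <- angle_deg * pi / 180
  img_t <- .affine_sample(img, dy, dx, flip, a, "bilinear")
  mask_t <- (.affine_sample(mask, dy, dx, flip, a, "nearest") >= 0.5) * 1
  list(image = pmin(pmax(img_t, 0), 1), mask = mask_t)
}

#' Mask-driven preprocessing chain
#'
#' The full evaluation-time chain: tight bounding box of the (possibly
#' AND-fused) lung mask, bicubic crop-resize to `size`, then 1% percentile
#' contrast stretch to `[0, 1]`.
#'
#' @param img `H x W` intensity matrix.
#' @param mask binary lung mask.
#' @param size output side length (default 512, the full-scale working
#'   resolution; tests use smaller sizes).
#' @return list with the preprocessed `image` and the `box` used.
#' @export
preprocess_image <- function(img, mask, size = 512) {
  box <- mask_to_bbox(mask)
  out <- crop_resize(img, box, size)
  list(image = contrast_stretch(out), box = box)
}

#' Preprocess a manifest of image/mask PNG pairs
#'
#' Reads a CSV manifest (columns `path`, `mask_path`, `label`), runs
#' [preprocess_image()] on every pair, writes the preprocessed PNGs to
#' `out_dir` and returns an audit table of the bounding boxes used.
#'
#' @param manifest_csv path to the manifest.
#' @param out_dir output directory.
#' @param size output side length.
#' @return data frame audit log (paths, labels, box coordinates),
#'   also written to `out_dir/audit.csv`.
#' @export
preprocess_manifest <- function(manifest_csv, out_dir, size = 512) {
  man <- utils::read.csv(manifest_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    img <- read_gray_png(man$path[i])
    mask <- (read_gray_png(man$mask_path[i]) >= 0.5) * 1
    pp <- preprocess_image(img, mask, size)
    out_path <- file.path(out_dir, basename(man$path[i]))
    png::writePNG(pp$image, out_path)
    rows[[i]] <- data.frame(path = out_path, label = man$label[i],
                            row_start = pp$box$row_start, row_end = pp$box$row_end,
                            col_start = pp$box$col_start, col_end = pp$box$col_end)
  }
  audit <- do.call(rbind, rows)
  utils::write.csv(audit, file.path(out_dir, "audit.csv"), row.names = FALSE)
  audit
}
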