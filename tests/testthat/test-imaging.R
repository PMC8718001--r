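# Imaging: bounding boxes, bicubic crop-resize, percentile stretch, and
# the affine augmentation contracts.

test_that("mask_to_bbox finds the tight half-open box", {
  m <- matrix(0, 10, 10)
  m[3:6, 4:8] <- 1   # rows 2-5, cols 3-7 in 0-based indexing
  box <- mask_to_bbox(m)
  expect_equal(box, list(row_start = 2L, row_end = 6L,
                         col_start = 3L, col_end = 8L))
  full <- matrix(1, 4, 5)
  expect_equal(mask_to_bbox(full),
               list(row_start = 0L, row_end = 4L, col_start = 0L, col_end = 5L))
  expect_error(mask_to_bbox(matrix(0, 3, 3)), "no foreground")
  # AND-fused boxes nest inside constituent boxes
  set.seed(1)
  for (i in 1:10) {
    a <- random_binary_mask(12, 12, 0.3); a[5, 5] <- 1
    b <- random_binary_mask(12, 12, 0.3); b[5, 5] <- 1
    bf <- mask_to_bbox(bitwise_and_masks(list(a, b)))
    ba <- mask_to_bbox(a)
    expect_gte(bf$row_start, ba$row_start); expect_lte(bf$row_end, ba$row_end)
    expect_gte(bf$col_start, ba$col_start); expect_lte(bf$col_end, ba$col_end)
  }
})

test_that("crop_resize is the identity at native size and preserves range", {
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  full <- list(row_start = 0L, row_end = 8L, col_start = 0L, col_end = 8L)
  expect_equal(crop_resize(img, full, 8), img, tolerance = 1e-12)
  # constant input, any scale
  cimg <- matrix(0.42, 6, 6)
  out <- crop_resize(cimg, mask_to_bbox(matrix(1, 6, 6)), 13)
  expect_equal(out, matrix(0.42, 13, 13), tolerance = 1e-9)
  # checkerboard upsampling stays within [0, 1] after clipping
  cb <- matrix(rep(c(0, 1), 8), 4, 4)
  up <- crop_resize(cb, mask_to_bbox(matrix(1, 4, 4)), 8)
  expect_true(all(up >= 0 & up <= 1))
  expect_error(crop_resize(img, list(row_start = 2L, row_end = 2L,
                                     col_start = 0L, col_end = 4L), 4),
               "non-degenerate")
})

test_that("contrast_stretch follows the percentile map and saturates", {
  ramp <- matrix(seq(0, 0.99, length.out = 100), 10, 10)  # values 0..0.99
  out <- contrast_stretch(ramp)
  p1 <- stats::quantile(ramp, 0.01, names = FALSE, type = 1)
  p99 <- stats::quantile(ramp, 0.99, names = FALSE, type = 1)
  mid <- which(abs(ramp - 0.5) < 1e-9)[1]
  expect_equal(out[mid], (0.5 - p1) / (p99 - p1), tolerance = 1e-9)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  # idempotent up to tolerance
  expect_lt(max(abs(contrast_stretch(out) - out)), 1e-6)
  # constant image convention
  expect_equal(contrast_stretch(matrix(0.3, 4, 4)), matrix(0, 4, 4))
})

test_that("augmentation applies one transform to both image and mask", {
  s <- gen_sample(0, 32, 32, seed = 3)
  ident <- apply_affine(s$image, s$mask)
  expect_equal(ident$image, s$image)
  expect_equal(ident$mask, s$mask, ignore_attr = TRUE)
  # double horizontal flip is the identity
  f1 <- apply_affine(s$image, s$mask, flip = TRUE)
  f2 <- apply_affine(f1$image, f1$mask, flip = TRUE)
  expect_equal(f2$image, s$image)
  expect_equal(f2$mask, s$mask, ignore_attr = TRUE)
  # +2 then -2 pixel shift restores the interior
  sh <- apply_affine(s$image, s$mask, dy = 2, dx = 2)
  back <- apply_affine(sh$image, sh$mask, dy = -2, dx = -2)
  interior_r <- 3:30; interior_c <- 3:30
  expect_equal(back$image[interior_r, interior_c],
               s$image[interior_r, interior_c])
  expect_equal(back$mask[interior_r, interior_c],
               s$mask[interior_r, interior_c], ignore_attr = TRUE)
  # foreground conservation up to boundary cropping
  n0 <- sum(s$mask)
  expect_gte(sum(sh$mask), n0 - 2 * 32 * 2)
  expect_true(all(sh$mask %in% c(0, 1)))
})

test_that("augment() draws within the spec ranges deterministically", {
  s <- gen_sample(2, 32, 32, seed = 4)
  spec <- augment_spec(max_shift_px = 2, hflip = TRUE, max_rotation_deg = 5,
                       seed = 11)
  a1 <- augment(s$image, s$mask, spec)
  a2 <- augment(s$image, s$mask, spec)
  expect_identical(a1, a2)
  expect_true(abs(a1$transform$dy) <= 2 && abs(a1$transform$dx) <= 2)
  expect_lte(abs(a1$transform$angle), 5 * pi / 180)
  expect_true(all(a1$image >= 0 & a1$image <= 1))
  expect_error(augment_spec(max_shift_px = 3), "max_shift_px")
  expect_error(augment_spec(max_rotation_deg = 10), "max_rotation_deg")
})

test_that("the preprocessing chain crops, resizes and stretches", {
  s <- gen_sample(0, 48, 48, seed = 5)
  pp <- preprocess_image(s$image, s$mask, size = 32)
  expect_equal(dim(pp$image), c(32L, 32L))
  expect_equal(min(pp$image), 0)
  expect_equal(max(pp$image), 1)
  # manifest-driven variant
  dir <- withr::local_tempdir()
  ds <- gen_samples(gen_labels(3, rep(1 / 3, 3), seed = 6), 48, 48, seed = 7)
  manifest <- write_samples(ds, file.path(dir, "raw"))
  audit <- preprocess_manifest(manifest, file.path(dir, "prep"), size = 32)
  expect_equal(nrow(audit), 3L)
  expect_true(all(file.exists(audit$path)))
  out <- read_gray_png(audit$path[1])
  expect_equal(dim(out), c(32L, 32L))
})
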