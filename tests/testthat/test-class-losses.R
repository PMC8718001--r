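# Classification losses: worked scalar examples, validation, equivalences
# and batch-statistic behaviour of the calibration gap.

test_that("entropy matches closed forms and respects bounds", {
  p <- matrix(c(1, 0, 0,
                1 / 3, 1 / 3, 1 / 3,
                0.5, 0.5, 0), 3, 3, byrow = TRUE)
  h <- entropy(p)
  expect_equal(h[1], 0, tolerance = 1e-5)
  expect_equal(h[2], log(3), tolerance = 1e-9)
  expect_equal(h[3], log(2), tolerance = 1e-9)
  set.seed(1)
  hp <- entropy(random_prob_batch(50, 4))
  expect_true(all(hp >= 0 & hp <= log(4) + 1e-9))
})

test_that("cce matches hand-computed values", {
  y <- one_hot(c(0L, 1L, 2L), 3)
  p <- matrix(c(1, 0, 0,
                0.2, 0.7, 0.1,
                1 / 3, 1 / 3, 1 / 3), 3, 3, byrow = TRUE)
  l <- cce(y, p)
  expect_equal(l$per_sample[1], 0, tolerance = 1e-5)
  expect_equal(l$per_sample[2], -log(0.7), tolerance = 1e-9)
  expect_equal(l$per_sample[3], log(3), tolerance = 1e-6)
  expect_equal(l$value, mean(l$per_sample))
  expect_error(cce(y, p[1:2, ]), "identical dimensions")
  bad <- p; bad[1, ] <- c(0.5, 0.2, 0.2)
  expect_error(cce(y, bad), "sum to 1")
})

test_that("label smoothing follows y(1-sigma) + sigma/K and keeps rows stochastic", {
  y <- one_hot(c(0L, 2L), 3)
  ys <- smooth_labels(y, 0.2)
  expect_equal(ys[1, ], c(0.8667, 0.0667, 0.0667), tolerance = 1e-3)
  expect_equal(rowSums(ys), c(1, 1))
  expect_equal(smooth_labels(y, 0), y)
  expect_error(smooth_labels(y, 1), "sigma")
  expect_error(smooth_labels(ys, 0.1), "one-hot")
})

test_that("focal loss down-weights easy samples and reduces to cce at gamma 0", {
  y <- one_hot(1L, 3)
  p <- matrix(c(0.2, 0.7, 0.1), 1, 3)
  expect_equal(categorical_focal(y, p, gamma = 2)$value,
               (1 - 0.7)^2 * -log(0.7), tolerance = 1e-9)
  expect_equal(categorical_focal(y, one_hot(1L, 3), gamma = 2)$value, 0,
               tolerance = 1e-5)
  set.seed(2)
  yr <- one_hot(sample(0:2, 20, replace = TRUE), 3)
  pr <- random_prob_batch(20, 3)
  expect_equal(categorical_focal(yr, pr, gamma = 0)$value, cce(yr, pr)$value,
               tolerance = 1e-9)
  expect_error(categorical_focal(y, p, gamma = -1), "gamma")
})

test_that("KL divergence handles zeros and collapses to cce on one-hot targets", {
  y <- matrix(c(0.5, 0.5, 0), 1, 3)
  p <- matrix(c(0.25, 0.25, 0.5), 1, 3)
  expect_equal(kl_divergence(y, p)$value, log(2), tolerance = 1e-9)
  expect_equal(kl_divergence(p, p)$value, 0, tolerance = 1e-9)
  set.seed(3)
  yr <- one_hot(sample(0:2, 30, replace = TRUE), 3)
  pr <- random_prob_batch(30, 3)
  expect_equal(kl_divergence(yr, pr)$value, cce(yr, pr)$value, tolerance = 1e-5)
})

test_that("categorical hinge matches the max-margin form", {
  expect_equal(categorical_hinge(one_hot(0L, 3),
                                 matrix(c(0.7, 0.2, 0.1), 1, 3))$value, 0.5)
  expect_equal(categorical_hinge(one_hot(1L, 3),
                                 matrix(c(0.6, 0.1, 0.3), 1, 3))$value, 1.5)
  expect_equal(categorical_hinge(one_hot(2L, 3), one_hot(2L, 3))$value, 0)
  expect_error(
    categorical_hinge(smooth_labels(one_hot(0L, 3), 0.2),
                      matrix(c(0.7, 0.2, 0.1), 1, 3)),
    "one-hot"
  )
})

test_that("calibration gap is |accuracy - mean argmax probability|", {
  # both rows correct with argmax probabilities 0.9 and 0.7
  y <- one_hot(c(0L, 1L), 3)
  p <- matrix(c(0.9, 0.05, 0.05,
                0.15, 0.7, 0.15), 2, 3, byrow = TRUE)
  expect_equal(calibration_gap(y, p), abs(1 - 0.8), tolerance = 1e-12)
  # 1 of 2 rows correct, argmax probabilities 0.8 and 0.6
  p2 <- matrix(c(0.8, 0.1, 0.1,
                 0.6, 0.3, 0.1), 2, 3, byrow = TRUE)
  expect_equal(calibration_gap(y, p2), abs(0.5 - 0.7), tolerance = 1e-12)
  expect_equal(calibration_gap(y, one_hot(c(0L, 1L), 3)), 0, tolerance = 1e-6)
  set.seed(4)
  for (i in 1:20) {
    yr <- one_hot(sample(0:2, 40, replace = TRUE), 3)
    pr <- random_prob_batch(40, 3)
    g <- calibration_gap(yr, pr)
    expect_gte(g, 0); expect_lte(g, 1)
    # batch statistic: invariant under row permutation
    ord <- sample(40)
    expect_equal(calibration_gap(yr[ord, ], pr[ord, ]), g)
  }
})

test_that("entropy regularization and calibrated composition are additive", {
  y <- one_hot(c(0L, 1L), 3)
  u <- matrix(1 / 3, 2, 3)
  expect_equal(entropy_regularized_cce(y, u, beta = 2)$value, -log(3),
               tolerance = 1e-5)
  set.seed(5)
  yr <- one_hot(sample(0:2, 25, replace = TRUE), 3)
  pr <- random_prob_batch(25, 3)
  expect_equal(entropy_regularized_cce(yr, pr, beta = 0)$value,
               cce(yr, pr)$value)
  g <- calibration_gap(yr, pr)
  expect_equal(calibrated_negative_entropy(yr, pr, beta = 0.5, lambda_ = 10)$value,
               entropy_regularized_cce(yr, pr, beta = 0.5)$value + 10 * g,
               tolerance = 1e-12)
  cal <- calibrate("hinge", lambda_ = 10)
  expect_equal(cal(yr, pr)$value,
               categorical_hinge(yr, pr)$value + 10 * g, tolerance = 1e-12)
  expect_error(calibrate("cce", lambda_ = -1), "lambda")
  expect_error(calibrate(entropy), "unsupported")
})

test_that("the loss registry exposes twelve losses with working defaults", {
  expect_length(classification_loss_names(), 12L)
  set.seed(6)
  y <- one_hot(sample(0:2, 30, replace = TRUE), 3)
  p <- random_prob_batch(30, 3)
  for (nm in classification_loss_names()) {
    v <- classification_loss(nm)(y, p)$value
    expect_true(is.finite(v), info = nm)
  }
  # calibrated-kl and calibrated-cce agree on one-hot targets at equal lambda
  expect_equal(classification_loss("calibrated_kl", lambda_ = 1)(y, p)$value,
               classification_loss("calibrated_cce", lambda_ = 1)(y, p)$value,
               tolerance = 1e-5)
})

test_that("per-sample losses are permutation invariant over the batch", {
  set.seed(7)
  y <- one_hot(sample(0:2, 35, replace = TRUE), 3)
  p <- random_prob_batch(35, 3)
  ord <- sample(35)
  for (nm in classification_loss_names()) {
    f <- classification_loss(nm)
    expect_equal(f(y[ord, ], p[ord, ])$value, f(y, p)$value,
                 tolerance = 1e-12, info = nm)
  }
})

test_that("losses can be configured from a file", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "focal", gamma = 2), path, auto_unbox = TRUE)
  f <- loss_from_config(path)
  y <- one_hot(1L, 3); p <- matrix(c(0.2, 0.7, 0.1), 1, 3)
  expect_equal(f(y, p)$value, categorical_focal(y, p, gamma = 2)$value)
})
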