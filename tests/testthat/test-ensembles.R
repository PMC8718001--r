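# Ensembles: voting/averaging algebra, simplex weight optimization against
# the grid-search oracle, stacking learnability, AND-fusion algebra.

make_stack <- function(mats) {
  M <- length(mats)
  out <- array(0, c(M, nrow(mats[[1]]), ncol(mats[[1]])))
  for (m in seq_len(M)) out[m, , ] <- mats[[m]]
  out
}

test_that("majority vote follows the modal argmax with the documented tie-break", {
  p0 <- matrix(c(0.6, 0.3, 0.1), 1, 3)
  p1 <- matrix(c(0.5, 0.4, 0.1), 1, 3)
  p2 <- matrix(c(0.1, 0.8, 0.1), 1, 3)
  expect_equal(majority_vote(make_stack(list(p0, p1, p2))), 0L)
  # all models identical
  expect_equal(majority_vote(make_stack(list(p2, p2))), 1L)
  # three-way tie decided by the highest mean probability (class 2 here)
  q0 <- matrix(c(0.50, 0.25, 0.25), 1, 3)
  q1 <- matrix(c(0.10, 0.46, 0.44), 1, 3)
  q2 <- matrix(c(0.10, 0.30, 0.60), 1, 3)
  expect_equal(majority_vote(make_stack(list(q0, q1, q2))), 2L)
  # invariance to model ordering
  set.seed(1)
  mats <- replicate(3, random_prob_batch(25, 3), simplify = FALSE)
  v <- majority_vote(make_stack(mats))
  expect_equal(majority_vote(make_stack(mats[c(3, 1, 2)])), v)
})

test_that("simple and weighted averaging obey their algebra", {
  set.seed(2)
  mats <- replicate(3, random_prob_batch(20, 3), simplify = FALSE)
  st <- make_stack(mats)
  avg <- simple_average(st)
  expect_equal(rowSums(avg), rep(1, 20), tolerance = 1e-9)
  expect_equal(simple_average(make_stack(list(mats[[1]], mats[[1]]))), mats[[1]])
  expect_equal(weighted_average(st, c(1, 0, 0)), mats[[1]])
  expect_equal(weighted_average(st, rep(1 / 3, 3)), avg, tolerance = 1e-12)
  two <- make_stack(list(one_hot(0L, 3), one_hot(1L, 3)))
  expect_equal(weighted_average(two, c(0.5, 0.5)),
               matrix(c(0.5, 0.5, 0), 1, 3))
  blend <- weighted_average(two, c(0.3764, 0.6236))
  expect_equal(blend, matrix(c(0.3764, 0.6236, 0), 1, 3), tolerance = 1e-12)
  expect_error(weighted_average(st, c(0.5, 0.5)), "one weight per model")
  expect_error(weighted_average(st, c(0.6, 0.6, -0.2)), "non-negative")
})

test_that("optimize_weights matches the 0.01-step grid oracle and beats vertices", {
  lab <- gen_labels(500, c(0.3, 0.4, 0.3), seed = 3)
  zoo <- gen_model_zoo(lab, c(0.85, 0.7, 0.55), agreement = 0.2, seed = 4)
  opt <- optimize_weights(zoo, lab)
  expect_true(opt$converged)
  expect_equal(sum(opt$w), 1, tolerance = 1e-9)
  expect_true(all(opt$w >= -1e-12))
  pt <- true_class_probs(zoo, lab)
  oracle <- grid_search_weights(pt)
  expect_lt(opt$log_loss, oracle$log_loss + 1e-3)
  single <- vapply(1:3, function(m) {
    log_loss(lab, matrix(zoo[m, , ], 500, 3))
  }, numeric(1))
  expect_lte(opt$log_loss, min(single) + 1e-6)
  # a perfect model and a noisy one: nearly all weight on the former
  perfect <- one_hot(lab, 3)
  noisy <- gen_prediction_batch(lab, 0.4, 0.5, seed = 5)
  opt2 <- optimize_weights(make_stack(list(perfect, noisy)), lab)
  expect_gt(opt2$w[1], 0.9)
  # identical models: objective is flat, combined equals single log loss
  opt3 <- optimize_weights(make_stack(list(noisy, noisy)), lab)
  expect_equal(opt3$log_loss, log_loss(lab, noisy), tolerance = 1e-9)
})

test_that("the stacker learns to trust an accurate constituent", {
  lab <- gen_labels(1000, c(0.3, 0.4, 0.3), seed = 6)
  zoo <- make_stack(list(gen_prediction_batch(lab, 0.98, 0.9, seed = 7),
                         gen_prediction_batch(lab, 0.45, 0.5, seed = 8),
                         gen_prediction_batch(lab, 0.45, 0.5, seed = 9)))
  st <- fit_stacker(zoo, lab, seed = 10)
  expect_equal(st$hidden_units, 9L)   # three-model default sizing
  # fresh evaluation zoo from the same generating process
  lab2 <- gen_labels(400, c(0.3, 0.4, 0.3), seed = 11)
  zoo2 <- make_stack(list(gen_prediction_batch(lab2, 0.98, 0.9, seed = 12),
                          gen_prediction_batch(lab2, 0.45, 0.5, seed = 13),
                          gen_prediction_batch(lab2, 0.45, 0.5, seed = 14)))
  p <- predict(st, zoo2)
  expect_equal(rowSums(p), rep(1, 400), tolerance = 1e-6)
  expect_gte(mean(max.col(p) - 1L == lab2), 0.95)
  # deterministic per seed
  st2 <- fit_stacker(zoo, lab, seed = 10)
  expect_equal(predict(st2, zoo2), p, tolerance = 1e-12)
  # five-model default sizing
  zoo5 <- make_stack(replicate(5, gen_prediction_batch(lab, 0.7, 0.7, seed = 15),
                               simplify = FALSE))
  expect_equal(fit_stacker(zoo5, lab, seed = 1, maxit = 5)$hidden_units, 15L)
})

test_that("bitwise AND fusion is the elementwise minimum with its algebra", {
  a <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE)
  b <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(bitwise_and_masks(list(a, b)),
               matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(bitwise_and_masks(list(a, a)), a)
  expect_equal(bitwise_and_masks(list(a, matrix(0, 2, 2))), matrix(0, 2, 2))
  set.seed(16)
  for (i in 1:20) {
    ms <- replicate(3, random_binary_mask(6, 6), simplify = FALSE)
    f <- bitwise_and_masks(ms)
    expect_equal(f, pmin(ms[[1]], pmin(ms[[2]], ms[[3]])))
    expect_equal(bitwise_and_masks(ms[c(2, 3, 1)]), f)           # commutative
    expect_equal(bitwise_and_masks(list(bitwise_and_masks(ms[1:2]), ms[[3]])),
                 f)                                               # associative
    for (m in ms) expect_true(all(f <= m))                        # subset
  }
  expect_error(bitwise_and_masks(list(a)), "two masks")
  expect_error(bitwise_and_masks(list(a, a * 0.5)), "0 and 1")
})

test_that("feature fusion reproduces the full-scale shape arithmetic", {
  # three (16,16,512) stacks concatenate to 1536 channels, reduced to 512
  stacks3 <- replicate(3, array(0, c(1, 16, 16, 512)), simplify = FALSE)
  cat3 <- concat_features(stacks3)
  expect_equal(dim(cat3), c(1, 16, 16, 1536))
  head3 <- fuse_features(stacks3, fused_channels = 512, seed = 1)
  expect_equal(head3$layers[[1]]$out_shape, c(16, 16, 512))
  # five stacks concatenate to 2560 channels
  stacks5 <- replicate(5, array(0, c(1, 16, 16, 512)), simplify = FALSE)
  expect_equal(dim(concat_features(stacks5))[4], 2560)
  # a tiny head produces row-stochastic predictions
  set.seed(17)
  tiny <- replicate(2, array(runif(3 * 4 * 4 * 8), c(3, 4, 4, 8)),
                    simplify = FALSE)
  headt <- fuse_features(tiny, seed = 2)
  p <- predict(headt, concat_features(tiny))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
})
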