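# Training module: network contracts (shapes, sigmoid/softmax ranges,
# parameter sharing), the training-loop schedule and checkpoint rules,
# and a scaled transfer-learning comparison.

test_that("the tiny segmenter meets its shape and range contracts", {
  seg <- build_segmenter(backbone_spec(), c(32L, 32L, 1L), seed = 1)
  expect_lt(network_n_params(seg), 50000)
  x <- array(stats::runif(2 * 32 * 32), c(2, 32, 32, 1))
  p <- predict(seg, x)
  expect_equal(dim(p), c(2L, 32L, 32L))
  expect_true(all(p > 0 & p < 1))            # sigmoid range, untrained
  # seeded init is deterministic
  seg2 <- build_segmenter(backbone_spec(), c(32L, 32L, 1L), seed = 1)
  expect_equal(predict(seg2, x), p, tolerance = 1e-15)
  expect_error(build_segmenter("resnet"), "backbone_spec")
  expect_error(build_segmenter(backbone_spec(), c(30L, 30L, 1L)), "pool2")
})

test_that("encoder truncation taps the segmenter's internal activations", {
  seg <- build_segmenter(backbone_spec(), c(32L, 32L, 1L), seed = 2)
  enc <- truncate_encoder(seg, "stage3")
  x <- array(stats::runif(3 * 32 * 32), c(3, 32, 32, 1))
  f_seg <- extract_features(seg, x, "stage3")
  f_enc <- extract_features(enc, x, "stage3")
  expect_equal(f_enc, f_seg, tolerance = 1e-15)
  expect_equal(dim(f_enc), c(3, 8, 8, 32))   # (H/4, W/4, widths[3])
  # shared parameters: mutating one view mutates the other
  old <- seg$params$enc1$W[1]
  enc$params$enc1$W[1] <- old + 1
  expect_equal(seg$params$enc1$W[1], old + 1)
  enc$params$enc1$W[1] <- old
  expect_error(truncate_encoder(seg, "stage9"), "stage")
})

test_that("the classifier head produces a 3-class softmax", {
  enc <- truncate_encoder(build_segmenter(backbone_spec(),
                                          c(32L, 32L, 1L), seed = 3))
  clf <- build_classifier(enc, n_classes = 3L, seed = 4)
  x <- array(stats::runif(5 * 32 * 32), c(5, 32, 32, 1))
  p <- predict(clf, x)
  expect_equal(dim(p), c(5L, 3L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-9)
  # deepest-convolutional-layer tap used for fusion
  f <- extract_features(clf, x, "dcl")
  expect_equal(dim(f), c(5, 8, 8, 32))
})

test_that("train() honours the schedule, checkpoint and determinism contracts", {
  labs <- gen_labels(60, c(0.3, 0.4, 0.3), seed = 5)
  ds <- gen_samples(labs, 32, 32, seed = 6)
  make_fit <- function() {
    enc <- truncate_encoder(build_segmenter(backbone_spec(),
                                            c(32L, 32L, 1L), seed = 7))
    clf <- build_classifier(enc, seed = 8)
    train(clf, ds$x, ds$labels,
          train_config("cce", optimizer = "adam", lr = 3e-3, epochs = 8,
                       patience = 2, seed = 9))
  }
  fit <- make_fit()
  h <- fit$history
  expect_equal(nrow(h), 8L)
  expect_true(all(diff(h$lr) <= 0))                       # non-increasing LR
  expect_equal(fit$best_epoch, which.min(h$val_loss))     # selection rule
  expect_lt(h$val_loss[fit$best_epoch], h$val_loss[1] + 1e-12)
  # determinism of the full run
  fit2 <- make_fit()
  expect_equal(fit2$history, h, tolerance = 1e-12)
  expect_error(train(fit$net, ds$x, ds$labels, list()), "train_config")
})

test_that("a short segmentation run learns the lung ellipses", {
  labs <- gen_labels(60, rep(1 / 3, 3), seed = 10)
  ds <- gen_samples(labs, 32, 32, seed = 11)
  seg <- build_segmenter(backbone_spec(), c(32L, 32L, 1L), seed = 12)
  fit <- train(seg, ds$x, ds$masks,
               train_config("bce", optimizer = "adam", lr = 3e-3, epochs = 4,
                            seed = 13))
  expect_lt(min(fit$history$val_loss), fit$history$val_loss[1])
  m <- evaluate_segmentation(fit, ds$x[1:10, , , , drop = FALSE],
                             ds$masks[1:10, , ])
  expect_gt(m["dice"], 0.7)
  # augmented training runs and stays finite
  fit2 <- train(seg, ds$x[1:20, , , , drop = FALSE], ds$masks[1:20, , ],
                train_config("tversky", optimizer = "adam", lr = 1e-3,
                             epochs = 1, seed = 14,
                             augment = augment_spec(seed = 15)))
  expect_true(all(is.finite(fit2$history$train_loss)))
})

test_that("every registered classification loss trains without numerical failure", {
  labs <- gen_labels(48, c(0.3, 0.4, 0.3), seed = 16)
  ds <- gen_samples(labs, 32, 32, seed = 17)
  enc <- truncate_encoder(build_segmenter(backbone_spec(),
                                          c(32L, 32L, 1L), seed = 18))
  for (nm in classification_loss_names()) {
    clf <- build_classifier(clone_network(enc), seed = 19)
    fit <- train(clf, ds$x, ds$labels,
                 train_config(nm, optimizer = "sgd", lr = 1e-3, epochs = 2,
                              seed = 20))
    expect_true(all(is.finite(fit$history$train_loss)), info = nm)
    expect_true(all(is.finite(fit$history$val_loss)), info = nm)
  }
})

test_that("segmentation pretraining does not slow learning (scaled transfer check)", {
  seg_ds <- gen_samples(gen_labels(80, rep(1 / 3, 3), seed = 21), 32, 32,
                        seed = 22)
  seg <- build_segmenter(backbone_spec(), c(32L, 32L, 1L), seed = 23)
  seg_fit <- train(seg, seg_ds$x, seg_ds$masks,
                   train_config("bce", optimizer = "adam", lr = 3e-3,
                                epochs = 6, seed = 24))
  labs <- gen_labels(150, c(0.3, 0.5, 0.2), seed = 25)
  ds <- gen_samples(labs, 32, 32, seed = 26)
  te_labs <- gen_labels(60, c(0.3, 0.5, 0.2), seed = 27)
  te <- gen_samples(te_labs, 32, 32, seed = 28)
  mccs <- function(encoder_fn, seeds) {
    vapply(seeds, function(s) {
      clf <- build_classifier(encoder_fn(), seed = s)
      fit <- train(clf, ds$x, ds$labels,
                   train_config("cce", optimizer = "adam", lr = 3e-3,
                                epochs = 12, seed = s))
      evaluate(fit, te$x, te$labels)$mcc
    }, numeric(1))
  }
  pre <- mccs(function() clone_network(truncate_encoder(seg_fit$net)), 31:33)
  rnd <- mccs(function() {
    truncate_encoder(build_segmenter(backbone_spec(), c(32L, 32L, 1L),
                                     seed = 99))
  }, 31:33)
  # at a fixed epoch budget the pretrained encoder must do at least as well
  expect_gte(stats::median(pre), stats::median(rnd) - 1e-9)
})
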