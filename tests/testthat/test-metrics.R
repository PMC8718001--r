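# Metrics: counting oracles, closed forms, and cross-checks against
# independent implementations (binom.test for Clopper-Pearson, pROC for
# AUROC).

test_that("confusion counts pairs and conserves the total", {
  cm <- confusion(c(0, 1, 2), c(1, 1, 1), 3)
  expect_equal(cm[, 2], c(1L, 1L, 1L))
  expect_equal(sum(cm), 3L)
  expect_equal(confusion(0:2, 0:2, 3), diag(3L) * 1L, ignore_attr = TRUE)
  expect_error(confusion(c(0, 3), c(0, 0), 3), "labels")
})

test_that("mcc matches the binary closed form and the perfect/degenerate cases", {
  expect_equal(mcc(diag(c(5L, 7L, 9L))), 1)
  # binary 2x2 [[40,10],[5,45]] against the textbook formula
  cm <- matrix(c(40L, 10L, 5L, 45L), 2, 2, byrow = TRUE)
  tp <- 45; tn <- 40; fp <- 10; fn <- 5
  manual <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(mcc(cm), manual, tolerance = 1e-12)
  # constant predictions: zero by convention
  expect_equal(mcc(matrix(c(10L, 0L, 20L, 0L), 2, 2, byrow = TRUE)), 0)
  expect_error(mcc(matrix(0L, 2, 2)), "empty")
  # independence: near zero on a uniform 200-sample table
  expect_lt(abs(mcc(matrix(50L, 2, 2))), 1e-12)
})

test_that("precision/recall/F use support-weighted one-vs-rest averaging", {
  expect_equal(unname(precision_recall_f(diag(c(3L, 4L)))), c(1, 1, 1))
  cm <- matrix(c(5L, 5L, 0L, 10L), 2, 2, byrow = TRUE)
  out <- precision_recall_f(cm)
  expect_equal(unname(out["recall"]), 0.75) # support-weighted mean of (0.5, 1)
  set.seed(1)
  for (i in 1:5) {
    truth <- sample(0:2, 200, replace = TRUE)
    pred <- sample(0:2, 200, replace = TRUE)
    out <- precision_recall_f(confusion(truth, pred, 3))
    bf <- brute_metrics(truth, pred, 3)
    expect_equal(unname(out["precision"]), bf$precision, tolerance = 1e-12)
    expect_equal(unname(out["recall"]), bf$recall, tolerance = 1e-12)
    expect_equal(unname(out["f_score"]), bf$f_score, tolerance = 1e-12)
  }
})

test_that("clopper_pearson agrees with binom.test and handles the boundaries", {
  for (s in c(0L, 3L, 50L, 97L, 100L)) {
    ci <- clopper_pearson(s, 100L, 0.95)
    bt <- stats::binom.test(s, 100L)$conf.int
    expect_equal(ci$low, bt[1], tolerance = 1e-9)
    expect_equal(ci$high, bt[2], tolerance = 1e-9)
  }
  expect_equal(clopper_pearson(0L, 10L)$low, 0)
  ci <- clopper_pearson(10L, 10L, 0.95)
  expect_equal(ci$high, 1)
  expect_equal(ci$low, 0.025^(1 / 10), tolerance = 1e-9)
  expect_error(clopper_pearson(5L, 3L), "successes")
})

test_that("the MCC interval maps through a binomial proportion and brackets the point", {
  ci <- mcc_clopper_pearson(0.9, 624L)
  expect_lte(ci["low"], 0.9)
  expect_gte(ci["high"], 0.9)
  expect_gte(ci["low"], -1); expect_lte(ci["high"], 1)
  expect_equal(unname(mcc_clopper_pearson(1, 50L)["high"]), 1)
})

test_that("auc_roc equals pROC on binary and behaves at the extremes", {
  skip_if_not_installed("pROC")
  set.seed(2)
  truth <- sample(0:1, 300, replace = TRUE)
  score <- stats::runif(300) + 0.5 * truth
  p <- cbind(1 - score / 2, score / 2)
  p <- p / rowSums(p)
  ours <- auc_roc(truth, p)
  # support-weighted one-vs-rest of a binary problem
  a1 <- as.numeric(pROC::auc(pROC::roc(truth, p[, 2], quiet = TRUE,
                                       direction = "<")))
  a0 <- as.numeric(pROC::auc(pROC::roc(1 - truth, p[, 1], quiet = TRUE,
                                       direction = "<")))
  w <- c(mean(truth == 0), mean(truth == 1))
  expect_equal(ours, w[1] * a0 + w[2] * a1, tolerance = 1e-9)
  # perfect ranking
  lab <- sample(0:2, 60, replace = TRUE)
  expect_equal(auc_roc(lab, one_hot(lab, 3)), 1)
  expect_error(auc_roc(rep(0, 10), random_prob_batch(10, 3)), "two classes")
})

test_that("auc_roc is a rank statistic and near 0.5 for uninformative scores", {
  set.seed(3)
  lab <- sample(0:2, 2000, replace = TRUE)
  p <- random_prob_batch(2000, 3)
  a <- auc_roc(lab, p)
  expect_lt(abs(a - 0.5), 0.03)
  # invariant under strictly monotone transform of the score columns
  expect_equal(auc_roc(lab, p^3), a, tolerance = 1e-12)
})

test_that("auc_pr is bounded, perfect at one, and near prevalence for noise", {
  set.seed(4)
  lab <- sample(0:2, 60, replace = TRUE)
  expect_equal(auc_pr(lab, one_hot(lab, 3)), 1)
  lab <- sample(0:1, 2000, replace = TRUE, prob = c(0.7, 0.3))
  p <- random_prob_batch(2000, 2)
  a <- auc_pr(lab, p)
  expect_gte(a, 0); expect_lte(a, 1)
  # support-weighted mix of per-class prevalences: 0.7^2 + 0.3^2
  expect_lt(abs(a - (0.7^2 + 0.3^2)), 0.05)
})

test_that("dice/iou/accuracy follow the counting definitions and identity", {
  a <- matrix(0, 4, 4); a[1, 1:4] <- 1           # |A| = 4
  b <- matrix(0, 4, 4); b[1, 1:3] <- 1; b[2, 1:3] <- 1  # |B| = 6, inter = 3
  out <- dice_iou_pixelacc(a, b)
  expect_equal(unname(out["dice"]), 0.6)
  expect_equal(unname(out["iou"]), 3 / 7)
  expect_equal(dice_iou_pixelacc(a, a), c(dice = 1, iou = 1, accuracy = 1))
  z <- matrix(0, 3, 3)
  expect_equal(unname(dice_iou_pixelacc(z, z)["dice"]), 1)
  expect_error(dice_iou_pixelacc(a, a * 0.5), "0 and 1")
})

test_that("metric_report populates every standard column coherently", {
  set.seed(5)
  lab <- sample(0:2, 120, replace = TRUE)
  p <- gen_prediction_batch(lab, 0.85, 0.8, seed = 6)
  rep <- metric_report(lab, p)
  for (f in c("accuracy", "auroc", "auprc", "precision", "recall", "f_score")) {
    expect_gte(rep[[f]], 0); expect_lte(rep[[f]], 1)
  }
  expect_lte(rep$mcc_ci["low"], rep$mcc)
  expect_gte(rep$mcc_ci["high"], rep$mcc)
  df <- as.data.frame(rep)
  expect_equal(ncol(df), 9L)
  path <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$accuracy, rep$accuracy, tolerance = 1e-9)
  rp <- roc_points(lab, p, 1)
  expect_true(all(diff(rp$tpr) >= 0))
  pp <- pr_points(lab, p, 1)
  expect_true(all(pp$precision >= 0 & pp$precision <= 1))
})
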