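# Classification and segmentation evaluation metrics: confusion matrix,
# multi-class Matthews correlation coefficient with an exact binomial
# interval, support-weighted one-vs-rest precision/recall/F, AUROC, AUPRC,
# and the pixel-overlap metrics Dice / IoU / accuracy.

#' Confusion matrix from label vectors
#'
#' @param true_labels,predicted_labels 0-based class-index vectors.
#' @param n_classes number of classes `K`.
#' @return `K x K` integer matrix; rows = true class, columns = predicted.
#' @export
confusion <- function(true_labels, predicted_labels, n_classes) {
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  K <- as.integer(n_classes)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(true_labels) < 1L) stop("labels must be non-empty", call. = FALSE)
  if (any(true_labels < 0L) || any(true_labels >= K) ||
      any(predicted_labels < 0L) || any(predicted_labels >= K)) {
    stop("labels must lie in [0, ", K, ")", call. = FALSE)
  }
  cm <- matrix(0L, K, K)
  for (i in seq_along(true_labels)) {
    cm[true_labels[i] + 1L, predicted_labels[i] + 1L] <-
      cm[true_labels[i] + 1L, predicted_labels[i] + 1L] + 1L
  }
  cm
}

#' Multi-class Matthews correlation coefficient
#'
#' The generalized correlation between true and predicted classes computed
#' from a confusion matrix: with `s` the sample total, `c` the trace,
#' `t_k` the true-class and `p_k` the predicted-class marginals,
#' \deqn{MCC = (c s - \sum_k p_k t_k) /
#'   \sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}.}
#' Lies in `[-1, 1]`; +1 for a perfect model. Returns 0 when a marginal
#' variance is zero (e.g. constant predictions).
#'
#' @param cm confusion matrix as from [confusion()].
#' @return scalar MCC.
#' @export
mcc <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0)) {
    stop("cm must be a square non-negative confusion matrix", call. = FALSE)
  }
  s <- sum(cm)
  if (s == 0) stop("confusion matrix is empty", call. = FALSE)
  cdiag <- sum(diag(cm))
  tk <- rowSums(cm)
  pk <- colSums(cm)
  num <- cdiag * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  min(max(num / den, -1), 1)   # guard the ratio against rounding overshoot
}

#' Support-weighted precision, recall and F-score
#'
#' One-vs-rest precision and recall per class, combined by support-weighted
#' averaging; the F-score is the per-class harmonic mean of precision and
#' recall, averaged with the same weights. Classes with no predicted
#' (resp. true) samples contribute precision (resp. recall) 0.
#'
#' @param cm confusion matrix as from [confusion()].
#' @return named numeric vector `c(precision, recall, f_score)`.
#' @export
precision_recall_f <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop("cm must be square", call. = FALSE)
  }
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / sum(support)
  c(precision = sum(w * prec), recall = sum(w * rec), f_score = sum(w * f))
}

#' Exact Clopper-Pearson binomial interval
#'
#' Equal-tailed exact interval for a binomial proportion from beta
#' quantiles: lower bound `qbeta(a/2, s, n-s+1)` (0 when `s = 0`), upper
#' bound `qbeta(1-a/2, s+1, n-s)` (1 when `s = n`).
#'
#' @param successes,trials non-negative counts, `successes <= trials`.
#' @param level confidence level in `(0, 1)` (default 0.95).
#' @return list with `low`, `high`, `successes`, `trials`, `level`.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  s <- as.integer(successes); n <- as.integer(trials)
  if (is.na(s) || is.na(n) || s < 0L || n < 1L || s > n) {
    stop("need 0 <= successes <= trials with trials >= 1", call. = FALSE)
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)", call. = FALSE)
  }
  a <- 1 - level
  low <- if (s == 0L) 0 else stats::qbeta(a / 2, s, n - s + 1)
  high <- if (s == n) 1 else stats::qbeta(1 - a / 2, s + 1, n - s)
  list(low = low, high = high, successes = s, trials = n, level = level)
}

#' Clopper-Pearson interval for an MCC value
#'
#' The MCC lies in `[-1, 1]` and is not itself a binomial proportion; this
#' helper maps it to `[0, 1]` via `(mcc + 1) / 2`, treats
#' `round(n * (mcc + 1) / 2)` as binomial successes out of `n` trials,
#' computes the exact Clopper-Pearson interval on that proportion and maps
#' it back with `2 b - 1`. This is one defensible named strategy for
#' attaching an exact binomial interval to the MCC, not a distributional
#' result for the MCC itself.
#'
#' @param mcc_value MCC in `[-1, 1]`.
#' @param n number of evaluated samples.
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)` in `[-1, 1]`.
#' @export
mcc_clopper_pearson <- function(mcc_value, n, level = 0.95) {
  if (mcc_value < -1 - 1e-9 || mcc_value > 1 + 1e-9) {
    stop("mcc must lie in [-1, 1]", call. = FALSE)
  }
  mcc_value <- min(max(mcc_value, -1), 1)
  ci <- clopper_pearson(round(n * (mcc_value + 1) / 2), n, level)
  c(low = 2 * ci$low - 1, high = 2 * ci$high - 1)
}

.binary_auc_rank <- function(pos, scores) {
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest area under the ROC curve
#'
#' Per-class ROC AUC (class-k column scored against the indicator
#' `true == k`) computed by the rank (Mann-Whitney) statistic, which equals
#' trapezoidal integration of the ROC curve with tie handling, combined by
#' support-weighted averaging over the classes present in the truth.
#'
#' @param true_labels 0-based class-index vector.
#' @param p `N x K` probability (or score) matrix; as a rank statistic the
#'   AUC needs no row normalization.
#' @return scalar AUROC.
#' @export
auc_roc <- function(true_labels, p) {
  if (!is.matrix(p) || !is.numeric(p) || anyNA(p)) {
    stop("p must be a numeric score matrix", call. = FALSE)
  }
  true_labels <- as.integer(true_labels)
  present <- sort(unique(true_labels))
  if (length(present) < 2L) {
    stop("AUROC needs at least two classes present in the truth", call. = FALSE)
  }
  aucs <- w <- numeric(0)
  for (k in present) {
    pos <- true_labels == k
    aucs <- c(aucs, .binary_auc_rank(pos, p[, k + 1L]))
    w <- c(w, sum(pos))
  }
  sum(aucs * w) / sum(w)
}

.binary_average_precision <- function(pos, scores) {
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]; scores <- scores[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  # evaluate only at the last index of each distinct threshold
  last <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(pos)
  sum(diff(c(0, rec)) * prec)
}

#' One-vs-rest area under the precision-recall curve
#'
#' Per-class PR AUC via step-wise interpolation (sum of precision times
#' recall increments over decreasing score thresholds), combined by
#' support-weighted averaging. For uninformative scores the per-class
#' value approaches the class prevalence.
#'
#' @inheritParams auc_roc
#' @return scalar AUPRC.
#' @export
auc_pr <- function(true_labels, p) {
  if (!is.matrix(p) || !is.numeric(p) || anyNA(p)) {
    stop("p must be a numeric score matrix", call. = FALSE)
  }
  true_labels <- as.integer(true_labels)
  present <- sort(unique(true_labels))
  if (length(present) < 2L) {
    stop("AUPRC needs at least two classes present in the truth", call. = FALSE)
  }
  aps <- w <- numeric(0)
  for (k in present) {
    pos <- true_labels == k
    aps <- c(aps, .binary_average_precision(pos, p[, k + 1L]))
    w <- c(w, sum(pos))
  }
  sum(aps * w) / sum(w)
}

#' Dice, IoU and pixel accuracy of two binary masks
#'
#' `dice = 2|A&B| / (|A| + |B|)`, `iou = |A&B| / |A or B|` (intersection
#' over union), accuracy = fraction of matching pixels. When both masks are empty, dice and iou are defined
#' as 1. The identity `dice = 2 iou / (1 + iou)` holds exactly, which is
#' why Dice values always dominate IoU values on the same masks.
#'
#' @param gt,pred binary masks of identical shape.
#' @return named numeric vector `c(dice, iou, accuracy)`.
#' @export
dice_iou_pixelacc <- function(gt, pred) {
  check_binary_mask(gt, "ground-truth mask")
  check_binary_mask(pred, "predicted mask")
  check_same_shape(gt, pred, "masks")
  inter <- sum(gt * pred)
  a <- sum(gt); b <- sum(pred)
  union <- a + b - inter
  dice <- if (a + b == 0) 1 else 2 * inter / (a + b)
  iou <- if (union == 0) 1 else inter / union
  c(dice = dice, iou = iou, accuracy = mean(gt == pred))
}

#' Full classification metric report
#'
#' Computes accuracy, AUROC, AUPRC, support-weighted precision/recall/F,
#' the multi-class MCC and its exact Clopper-Pearson interval (see
#' [mcc_clopper_pearson()]) from true labels and predicted probabilities.
#'
#' @param true_labels 0-based class-index vector.
#' @param p `N x K` probability batch.
#' @param level confidence level for the MCC interval.
#' @return object of class `metric_report` (a named list).
#' @export
metric_report <- function(true_labels, p, level = 0.95) {
  check_prob_batch(p)
  true_labels <- as.integer(true_labels)
  if (length(true_labels) != nrow(p)) {
    stop("labels and probability rows must match", call. = FALSE)
  }
  pred <- row_argmax(p)
  cm <- confusion(true_labels, pred, ncol(p))
  prf <- precision_recall_f(cm)
  m <- mcc(cm)
  structure(list(
    accuracy = mean(pred == true_labels),
    auroc = auc_roc(true_labels, p),
    auprc = auc_pr(true_labels, p),
    precision = unname(prf["precision"]),
    recall = unname(prf["recall"]),
    f_score = unname(prf["f_score"]),
    mcc = m,
    mcc_ci = mcc_clopper_pearson(m, length(true_labels), level),
    confusion = cm,
    n = length(true_labels)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Classification metrics (n = ", x$n, ")\n", sep = "")
  for (f in c("accuracy", "auroc", "auprc", "precision", "recall", "f_score", "mcc")) {
    cat(sprintf("  %-9s %.4f\n", f, x[[f]]))
  }
  cat(sprintf("  mcc 95%% CI (%.4f, %.4f)\n", x$mcc_ci["low"], x$mcc_ci["high"]))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(
    accuracy = x$accuracy, auroc = x$auroc, auprc = x$auprc,
    precision = x$precision, recall = x$recall, f_score = x$f_score,
    mcc = x$mcc, mcc_ci_low = x$mcc_ci["low"], mcc_ci_high = x$mcc_ci["high"],
    row.names = NULL
  )
}

#' Write a metric report to disk
#'
#' Writes JSON (full report) or CSV (one row with the standard metric
#' columns) depending on the file extension.
#'
#' @param report a `metric_report`.
#' @param path output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- report[c("accuracy", "auroc", "auprc", "precision", "recall",
                    "f_score", "mcc", "n")]
    out$mcc_ci <- unname(report$mcc_ci)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}

#' ROC and PR curve point lists
#'
#' One-vs-rest curve points for a single class, suitable for CSV export
#' and plotting.
#'
#' @inheritParams auc_roc
#' @param class 0-based class index.
#' @return data frame of curve points (`fpr`/`tpr` for ROC,
#'   `recall`/`precision` for PR) ordered by threshold.
#' @export
roc_points <- function(true_labels, p, class) {
  pos <- as.integer(true_labels) == class
  scores <- p[, class + 1L]
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  data.frame(threshold = scores[ord], fpr = fp / sum(!pos), tpr = tp / sum(pos))
}

#' @rdname roc_points
#' @export
pr_points <- function(true_labels, p, class) {
  pos <- as.integer(true_labels) == class
  scores <- p[, class + 1L]
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  data.frame(threshold = scores[ord], recall = tp / sum(pos),
             precision = tp / (tp + fp))
}
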