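# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force counting, closed forms, and
# central finite differences.

# central finite-difference gradient of a scalar function of a matrix
numeric_gradient <- function(fn, z, h = 1e-5) {
  g <- z
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- zp[i] + h
    zm <- z; zm[i] <- zm[i] - h
    g[i] <- (fn(zp) - fn(zm)) / (2 * h)
  }
  g
}

# number of 4-connected foreground components, by BFS flood fill
count_components_4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] == 1 && lab[i, j] == 0L) {
        n <- n + 1L
        queue <- list(c(i, j))
        lab[i, j] <- n
        while (length(queue)) {
          cur <- queue[[1]]; queue <- queue[-1]
          for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
            a <- cur[1] + d[1]; b <- cur[2] + d[2]
            if (a >= 1 && a <= nrow(mask) && b >= 1 && b <= ncol(mask) &&
                mask[a, b] == 1 && lab[a, b] == 0L) {
              lab[a, b] <- n
              queue <- c(queue, list(c(a, b)))
            }
          }
        }
      }
    }
  }
  n
}

# brute-force classification metrics recomputed from raw label pairs
brute_metrics <- function(truth, pred, K) {
  n <- length(truth)
  acc <- mean(truth == pred)
  prec <- rec <- f <- w <- numeric(K)
  for (k in 0:(K - 1)) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    prec[k + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f[k + 1] <- if (prec[k + 1] + rec[k + 1] > 0) {
      2 * prec[k + 1] * rec[k + 1] / (prec[k + 1] + rec[k + 1])
    } else 0
    w[k + 1] <- sum(truth == k) / n
  }
  # MCC via the covariance form, computed directly from indicator vectors
  cov_xy <- 0; cov_xx <- 0; cov_yy <- 0
  for (k in 0:(K - 1)) {
    x <- as.numeric(truth == k)
    y <- as.numeric(pred == k)
    cov_xy <- cov_xy + sum((x - mean(x)) * (y - mean(y)))
    cov_xx <- cov_xx + sum((x - mean(x))^2)
    cov_yy <- cov_yy + sum((y - mean(y))^2)
  }
  mcc <- if (cov_xx > 0 && cov_yy > 0) cov_xy / sqrt(cov_xx * cov_yy) else 0
  list(accuracy = acc, precision = sum(w * prec), recall = sum(w * rec),
       f_score = sum(w * f), mcc = mcc)
}

# exhaustive simplex grid search for ensemble weights (step 0.01, M = 3)
grid_search_weights <- function(ptrue, step = 0.01) {
  best <- Inf
  best_w <- NULL
  for (w1 in seq(0, 1, step)) {
    for (w2 in seq(0, 1 - w1, step)) {
      w <- c(w1, w2, 1 - w1 - w2)
      ll <- mean(-log(pmax(ptrue %*% w, 1e-7)))
      if (ll < best) { best <- ll; best_w <- w }
    }
  }
  list(w = best_w, log_loss = best)
}

# probability that the true class appears in each row, per model: n x M
true_class_probs <- function(stack, labels) {
  M <- dim(stack)[1]; n <- dim(stack)[2]
  vapply(seq_len(M), function(m) {
    pm <- matrix(stack[m, , ], n, dim(stack)[3])
    pm[cbind(seq_len(n), labels + 1L)]
  }, numeric(n))
}

random_prob_batch <- function(n, K) {
  m <- matrix(stats::rexp(n * K), n, K)
  m / rowSums(m)
}

random_binary_mask <- function(h, w, p = 0.4) {
  matrix(stats::rbinom(h * w, 1, p), h, w)
}

random_soft_mask <- function(h, w) {
  matrix(stats::runif(h * w), h, w)
}
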