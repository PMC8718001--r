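# Classification losses.
#
# All losses operate on an N x K probability batch `p` (rows on the simplex,
# typically softmax outputs) and an N x K target batch `y` (one-hot unless
# label smoothing has been applied). Values are in nats; per-sample losses
# are averaged over the batch and any calibration penalty is a single
# batch-level scalar added after that reduction. The calibration penalty is
# the absolute difference between batch accuracy and the mean probability
# assigned to the predicted class; it pulls confidence toward accuracy and
# penalizes loss decreases that are not matched by accuracy changes.

new_loss_value <- function(per_sample, batch_term = 0) {
  structure(
    list(value = mean(per_sample) + batch_term, per_sample = per_sample),
    class = "loss_value"
  )
}

#' @export
print.loss_value <- function(x, ...) {
  cat("<loss_value> ", format(x$value, digits = 6),
      " (mean over ", length(x$per_sample), " samples)\n", sep = "")
  invisible(x)
}

#' @export
as.double.loss_value <- function(x, ...) x$value

#' Shannon entropy of each predicted distribution
#'
#' \eqn{H(p) = -\sum_k p_k \log p_k} per row, in nats, with
#' \eqn{0 \log 0 := 0}. Peaked (confident) distributions have low entropy;
#' the uniform distribution attains the maximum \eqn{\log K}.
#'
#' @param p an `N x K` probability matrix (see [check_prob_batch()]).
#' @return length-`N` vector of entropies in `[0, log K]`.
#' @export
#' @examples
#' entropy(matrix(c(1, 0, 0, 1/3, 1/3, 1/3), 2, 3, byrow = TRUE))
entropy <- function(p) {
  check_prob_batch(p)
  -rowSums(p * log(clip_prob(p)))
}

#' Categorical cross-entropy loss
#'
#' Per-sample \eqn{-\sum_k y_k \log p_k} with probabilities clipped to
#' \eqn{[\epsilon, 1-\epsilon]}, \eqn{\epsilon = 10^{-7}}, averaged over the
#' batch.
#'
#' @param y `N x K` target batch (one-hot or smoothed).
#' @param p `N x K` probability batch.
#' @return a `loss_value` (fields `value`, `per_sample`).
#' @export
cce <- function(y, p) {
  check_target_batch(y); check_prob_batch(p)
  check_same_shape(y, p, "target and probability batches")
  new_loss_value(-rowSums(y * log(clip_prob(p))))
}

#' Label smoothing
#'
#' Replaces one-hot targets by \eqn{y(1-\sigma) + \sigma/K}, spreading a
#' mass \eqn{\sigma} uniformly over the classes. Rows still sum to one.
#'
#' @param y one-hot `N x K` target batch.
#' @param sigma smoothing factor in `[0, 1)`.
#' @return smoothed target batch.
#' @export
smooth_labels <- function(y, sigma) {
  check_target_batch(y)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0 || sigma >= 1) {
    stop("sigma must lie in [0, 1)", call. = FALSE)
  }
  if (!is_one_hot(y)) stop("smooth_labels expects one-hot targets", call. = FALSE)
  y * (1 - sigma) + sigma / ncol(y)
}

#' Categorical focal loss
#'
#' Per-sample \eqn{-\sum_k y_k (1-p_k)^\gamma \log p_k}. The modulating
#' factor \eqn{(1-p_k)^\gamma} down-weights easy (high-probability) samples
#' so training emphasises hard and minority-class samples; at
#' \eqn{\gamma = 0} it reduces exactly to [cce()].
#'
#' @inheritParams cce
#' @param gamma focusing exponent, `>= 0` (default 1).
#' @return a `loss_value`.
#' @export
categorical_focal <- function(y, p, gamma = 1) {
  check_target_batch(y); check_prob_batch(p)
  check_same_shape(y, p, "target and probability batches")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0) {
    stop("gamma must be >= 0", call. = FALSE)
  }
  pc <- clip_prob(p)
  new_loss_value(-rowSums(y * (1 - p)^gamma * log(pc)))
}

#' Kullback-Leibler divergence loss
#'
#' Per-sample \eqn{\sum_k y_k \log(y_k / p_k)} with \eqn{0 \log(0/\cdot):=0}
#' and clipped denominators. Coincides with [cce()] when `y` is one-hot
#' (the \eqn{\sum y \log y} term vanishes).
#'
#' @inheritParams cce
#' @return a `loss_value`.
#' @export
kl_divergence <- function(y, p) {
  check_target_batch(y); check_prob_batch(p)
  check_same_shape(y, p, "target and probability batches")
  terms <- y * (log(clip_prob(y)) - log(clip_prob(p)))
  terms[y == 0] <- 0
  new_loss_value(rowSums(terms))
}

#' Categorical Hinge loss
#'
#' Max-margin loss \eqn{\max(\mathrm{negative} - \mathrm{positive} + 1, 0)}
#' with \eqn{\mathrm{negative} = \max_k (1-y_k) p_k} (best wrong-class
#' score) and \eqn{\mathrm{positive} = \sum_k y_k p_k} (true-class score).
#' Requires strictly one-hot targets.
#'
#' @inheritParams cce
#' @return a `loss_value`.
#' @export
categorical_hinge <- function(y, p) {
  check_target_batch(y); check_prob_batch(p)
  check_same_shape(y, p, "target and probability batches")
  if (!is_one_hot(y)) {
    stop("categorical_hinge requires one-hot targets", call. = FALSE)
  }
  pn <- p
  pn[y == 1] <- -Inf
  negative <- apply(pn, 1L, max)
  positive <- rowSums(y * p)
  new_loss_value(pmax(negative - positive + 1, 0))
}

#' Batch calibration gap
#'
#' The absolute difference between batch accuracy (mean of the per-sample
#' correctness indicator) and batch confidence (mean probability assigned
#' to the predicted, i.e. argmax, class). A perfectly calibrated batch has
#' gap 0: its mean confidence matches its accuracy. Computed per mini-batch
#' and used as the additive `lambda * gap` penalty of every calibrated loss.
#'
#' @param y one-hot `N x K` target batch (argmax defines the true class).
#' @param p `N x K` probability batch.
#' @return scalar gap in `[0, 1]`.
#' @export
calibration_gap <- function(y, p) {
  check_target_batch(y); check_prob_batch(p)
  check_same_shape(y, p, "target and probability batches")
  if (!is_one_hot(y)) {
    stop("calibration_gap requires one-hot targets", call. = FALSE)
  }
  pred <- row_argmax(p)
  truth <- row_argmax(y)
  acc <- mean(pred == truth)
  conf <- mean(p[cbind(seq_len(nrow(p)), pred + 1L)])
  abs(acc - conf)
}

#' Entropy-regularized categorical cross-entropy
#'
#' Adds the negative entropy of the predictions to the negative
#' log-likelihood: per-sample \eqn{-\sum_k y_k \log p_k - \beta H(p)}.
#' Peaked (over-confident) output distributions are penalized, which
#' counteracts over-fitting to a dominant class; `beta` controls the
#' penalty intensity (default 2). The same term can serve as an output
#' activity regularizer; under the batch-mean reduction used here the two
#' deployments are numerically identical. May be negative for large `beta`.
#'
#' @inheritParams cce
#' @param beta entropy-penalty weight (default 2).
#' @return a `loss_value`.
#' @export
entropy_regularized_cce <- function(y, p, beta = 2) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    stop("beta must be a finite scalar", call. = FALSE)
  }
  base <- cce(y, p)
  new_loss_value(base$per_sample - beta * entropy(p))
}

#' Calibrated negative entropy loss
#'
#' [entropy_regularized_cce()] plus `lambda` times the batch
#' [calibration_gap()]. Defaults `beta = 0.001`, `lambda = 10`.
#'
#' @inheritParams entropy_regularized_cce
#' @param lambda_ calibration weight, `>= 0` (default 10).
#' @return a `loss_value`.
#' @export
calibrated_negative_entropy <- function(y, p, beta = 0.001, lambda_ = 10) {
  if (!is.numeric(lambda_) || length(lambda_) != 1L || lambda_ < 0) {
    stop("lambda_ must be >= 0", call. = FALSE)
  }
  base <- entropy_regularized_cce(y, p, beta = beta)
  new_loss_value(base$per_sample, batch_term = lambda_ * calibration_gap(y, p))
}

#' Build a calibrated loss from a base loss
#'
#' Returns a function computing `base(y, p) + lambda_ * calibration_gap(y, p)`.
#' Supported bases: `"cce"` (default `lambda_ = 10`), `"kl"` (default 1),
#' `"focal"` (defaults `gamma = 1`, `lambda_ = 1`) and `"hinge"` (default 10).
#'
#' @param base_loss base-loss name or one of the functions [cce()],
#'   [kl_divergence()], [categorical_focal()], [categorical_hinge()].
#' @param lambda_ calibration weight; `NULL` picks the base-specific default.
#' @param gamma focusing exponent, used only for the focal base.
#' @return a function `f(y, p)` returning a `loss_value`.
#' @export
#' @examples
#' cal_cce <- calibrate("cce", lambda_ = 10)
calibrate <- function(base_loss, lambda_ = NULL, gamma = 1) {
  name <- if (is.character(base_loss)) {
    match.arg(base_loss, c("cce", "kl", "focal", "hinge"))
  } else if (identical(base_loss, cce)) "cce"
  else if (identical(base_loss, kl_divergence)) "kl"
  else if (identical(base_loss, categorical_focal)) "focal"
  else if (identical(base_loss, categorical_hinge)) "hinge"
  else stop("unsupported base loss for calibration", call. = FALSE)
  lambda_ <- lambda_ %||% switch(name, cce = 10, kl = 1, focal = 1, hinge = 10)
  if (!is.numeric(lambda_) || length(lambda_) != 1L || lambda_ < 0) {
    stop("lambda_ must be >= 0", call. = FALSE)
  }
  base_fn <- switch(name,
    cce = cce,
    kl = kl_divergence,
    focal = function(y, p) categorical_focal(y, p, gamma = gamma),
    hinge = categorical_hinge
  )
  function(y, p) {
    b <- base_fn(y, p)
    new_loss_value(b$per_sample, batch_term = lambda_ * calibration_gap(y, p))
  }
}

# ---------------------------------------------------------------------------
# Loss registry

.CLASS_LOSSES <- c(
  "cce", "entropy_reg_cce", "kl", "focal", "hinge",
  "smoothed_cce", "smoothed_focal",
  "calibrated_cce", "calibrated_kl", "calibrated_focal", "calibrated_hinge",
  "calibrated_negative_entropy"
)

#' Names of the registered classification losses
#'
#' The twelve batch losses available by name: the four standard losses
#' (`cce`, `kl`, `focal`, `hinge`), their label-smoothed variants
#' (`smoothed_cce`, `smoothed_focal`, both `sigma = 0.2`), the
#' entropy-regularized cross-entropy (`entropy_reg_cce`, `beta = 2`), the
#' four calibrated losses (`calibrated_cce`, `lambda = 10`; `calibrated_kl`,
#' `lambda = 1`; `calibrated_focal`, `gamma = lambda = 1`;
#' `calibrated_hinge`, `lambda = 10`) and the calibrated negative entropy
#' loss (`beta = 0.001`, `lambda = 10`).
#'
#' @return character vector of loss names.
#' @export
classification_loss_names <- function() .CLASS_LOSSES

#' Look up a classification loss by name
#'
#' Returns a function `f(y, p) -> loss_value` with the registry's default
#' hyperparameters, overridable through `...` (`beta`, `lambda_`, `gamma`,
#' `sigma` as applicable).
#'
#' @param name one of [classification_loss_names()].
#' @param ... hyperparameter overrides.
#' @return loss function of `(y, p)`.
#' @export
classification_loss <- function(name, ...) {
  name <- match.arg(name, .CLASS_LOSSES)
  dots <- list(...)
  arg <- function(key, default) dots[[key]] %||% default
  switch(name,
    cce = cce,
    kl = kl_divergence,
    hinge = categorical_hinge,
    focal = {
      g <- arg("gamma", 1)
      function(y, p) categorical_focal(y, p, gamma = g)
    },
    entropy_reg_cce = {
      b <- arg("beta", 2)
      function(y, p) entropy_regularized_cce(y, p, beta = b)
    },
    smoothed_cce = {
      s <- arg("sigma", 0.2)
      function(y, p) cce(smooth_labels(y, s), p)
    },
    smoothed_focal = {
      s <- arg("sigma", 0.2); g <- arg("gamma", 1)
      function(y, p) categorical_focal(smooth_labels(y, s), p, gamma = g)
    },
    calibrated_cce = calibrate("cce", lambda_ = arg("lambda_", 10)),
    calibrated_kl = calibrate("kl", lambda_ = arg("lambda_", 1)),
    calibrated_focal = calibrate("focal", lambda_ = arg("lambda_", 1),
                                 gamma = arg("gamma", 1)),
    calibrated_hinge = calibrate("hinge", lambda_ = arg("lambda_", 10)),
    calibrated_negative_entropy = {
      b <- arg("beta", 0.001); l <- arg("lambda_", 10)
      function(y, p) calibrated_negative_entropy(y, p, beta = b, lambda_ = l)
    }
  )
}

#' Read a loss configuration file
#'
#' Reads a YAML (or JSON) file with fields `name` plus optional
#' hyperparameters (`beta`, `lambda_`, `gamma`, `sigma`) and returns the
#' corresponding loss function.
#'
#' @param path path to the configuration file.
#' @return loss function of `(y, p)`.
#' @export
loss_from_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  }
  if (is.null(cfg$name)) stop("loss config must have a 'name' field", call. = FALSE)
  do.call(classification_loss, c(list(name = cfg$name),
                                 cfg[setdiff(names(cfg), "name")]))
}
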