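# Prediction-level and model-level ensembles.
#
# A prediction set is an M x N x K array of probability matrices from M
# models over the same N samples (see gen_model_zoo()). All combiners
# preserve row-stochasticity.

check_prediction_set <- function(stack, min_models = 2L) {
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    stop("prediction set must be an M x N x K array", call. = FALSE)
  }
  M <- dim(stack)[1]
  if (M < min_models) {
    stop("prediction set needs at least ", min_models, " models", call. = FALSE)
  }
  for (m in seq_len(M)) {
    check_prob_batch(matrix(stack[m, , ], dim(stack)[2], dim(stack)[3]))
  }
  invisible(stack)
}

.slice <- function(stack, m) {
  matrix(stack[m, , ], dim(stack)[2], dim(stack)[3])
}

#' Majority-vote ensemble
#'
#' Per sample, the modal argmax class over the models. Ties are broken by
#' the highest mean probability across models, then by the lowest class
#' index; the result is therefore independent of model ordering.
#'
#' @param stack `M x N x K` prediction array.
#' @return integer vector of 0-based predicted classes.
#' @export
majority_vote <- function(stack) {
  check_prediction_set(stack)
  M <- dim(stack)[1]; n <- dim(stack)[2]; K <- dim(stack)[3]
  votes <- matrix(0L, n, K)
  for (m in seq_len(M)) {
    am <- row_argmax(.slice(stack, m))
    idx <- cbind(seq_len(n), am + 1L)
    votes[idx] <- votes[idx] + 1L
  }
  meanp <- simple_average(stack)
  out <- integer(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) {
      top <- top[order(-meanp[i, top], top)]
    }
    out[i] <- top[1L] - 1L
  }
  out
}

#' Simple averaging ensemble
#'
#' Element-wise mean of the model probability matrices.
#'
#' @inheritParams majority_vote
#' @return `N x K` probability matrix.
#' @export
simple_average <- function(stack) {
  check_prediction_set(stack)
  out <- matrix(0, dim(stack)[2], dim(stack)[3])
  for (m in seq_len(dim(stack)[1])) out <- out + .slice(stack, m)
  out / dim(stack)[1]
}

#' Weighted averaging ensemble
#'
#' Convex combination `sum_m w_m * slice_m` of the model probability
#' matrices; weights must be non-negative and sum to one, so rows remain
#' on the simplex. A vertex weight vector reproduces the corresponding
#' model exactly; uniform weights reproduce [simple_average()].
#'
#' @inheritParams majority_vote
#' @param w length-`M` weight vector on the probability simplex.
#' @return `N x K` probability matrix.
#' @export
weighted_average <- function(stack, w) {
  check_prediction_set(stack)
  M <- dim(stack)[1]
  if (length(w) != M) stop("need one weight per model", call. = FALSE)
  if (any(w < -1e-9) || abs(sum(w) - 1) > 1e-6) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  out <- matrix(0, dim(stack)[2], dim(stack)[3])
  for (m in seq_len(M)) out <- out + w[m] * .slice(stack, m)
  out
}

#' Multi-class log loss of a probability matrix
#'
#' Mean of `-log p[i, true_i]` with clipped probabilities; the objective
#' minimized by [optimize_weights()].
#'
#' @param labels 0-based class-index vector.
#' @param p `N x K` probability matrix.
#' @return scalar log loss (nats).
#' @export
log_loss <- function(labels, p) {
  labels <- as.integer(labels)
  mean(-log(clip_prob(p[cbind(seq_len(nrow(p)), labels + 1L)])))
}

# Euclidean projection of v onto the probability simplex (Duchi et al.).
.project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

#' Optimize ensemble weights by constrained log-loss minimization
#'
#' Finds the weight vector on the probability simplex (non-negative,
#' summing to one) that minimizes the multi-class log loss of the weighted
#' average of the model predictions. The objective is convex in the
#' weights; it is minimized by projected-gradient descent with Armijo
#' backtracking from a uniform start, so the solution is a global optimum
#' and its log loss can never exceed that of the best single model (a
#' simplex vertex). Non-convergence is reported via the `converged` flag
#' together with the best weights found.
#'
#' @inheritParams majority_vote
#' @param labels 0-based true-class vector used to score the blend.
#'   Which predictions/labels to optimize on (validation or test) is the
#'   caller's choice.
#' @param max_iter iteration budget.
#' @param tol stop when the objective improvement falls below this.
#' @return list with `w` (weights), `log_loss` (achieved), `converged`.
#' @export
optimize_weights <- function(stack, labels, max_iter = 500L, tol = 1e-12) {
  check_prediction_set(stack)
  labels <- as.integer(labels)
  M <- dim(stack)[1]; n <- dim(stack)[2]
  if (length(labels) != n) stop("labels must match sample count", call. = FALSE)
  # per-model probability assigned to the true class: n x M
  ptrue <- vapply(seq_len(M), function(m) {
    .slice(stack, m)[cbind(seq_len(n), labels + 1L)]
  }, numeric(n))

  obj <- function(w) mean(-log(pmax(ptrue %*% w, .PROB_EPS)))
  grad <- function(w) {
    blend <- pmax(ptrue %*% w, .PROB_EPS)
    -colMeans(ptrue / as.vector(blend))
  }

  w <- rep(1 / M, M)
  f <- obj(w)
  stalled <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(w)
    step <- 1
    repeat {
      w_new <- .project_simplex(w - step * g)
      f_new <- obj(w_new)
      if (f_new <= f - 1e-4 * sum(g * (w - w_new))) break
      step <- step / 2
      if (step < 1e-12) { stalled <- TRUE; break }
    }
    if (stalled) break
    done <- f - f_new < tol && sqrt(sum((w - w_new)^2)) < 1e-10
    w <- w_new; f <- f_new
    if (done) break
  }
  # first-order optimality on the simplex: min_j g_j >= <g, w>
  g <- grad(w)
  converged <- min(g) >= sum(g * w) - 1e-7
  if (!converged) {
    warning("weight optimization did not fully converge; returning best found")
  }
  list(w = as.vector(w), log_loss = f, converged = converged)
}

# --------------------------------------------------------------------------
# Stacking meta-learner

#' Fit a stacking meta-learner on model predictions
#'
#' Concatenates the M model probability matrices into an `N x (M K)` input
#' and fits a single-hidden-layer network with a K-unit softmax output
#' (via `nnet`). The base predictions are fixed inputs and are never
#' refit. Hidden width defaults to 9 for three models and 15 for five
#' models, otherwise `3 M`. Deterministic per seed.
#'
#' @inheritParams optimize_weights
#' @param hidden_units hidden-layer width; `NULL` for the default sizing.
#' @param seed integer RNG seed for the initial weights.
#' @param maxit optimizer iteration cap.
#' @return object of class `stacker`.
#' @export
fit_stacker <- function(stack, labels, hidden_units = NULL, seed = 1,
                        maxit = 300L) {
  check_prediction_set(stack)
  labels <- as.integer(labels)
  M <- dim(stack)[1]; n <- dim(stack)[2]; K <- dim(stack)[3]
  if (length(labels) != n) stop("labels must match sample count", call. = FALSE)
  hidden_units <- hidden_units %||% switch(as.character(M), "3" = 9L, "5" = 15L, 3L * M)
  x <- do.call(cbind, lapply(seq_len(M), function(m) .slice(stack, m)))
  y <- one_hot(labels, K)
  fit <- with_seed(seed, {
    nnet::nnet(x, y, size = hidden_units, softmax = TRUE, maxit = maxit,
               decay = 1e-4, trace = FALSE)
  })
  structure(list(fit = fit, n_models = M, n_classes = K,
                 hidden_units = hidden_units),
            class = "stacker")
}

#' @export
print.stacker <- function(x, ...) {
  cat("<stacker> ", x$n_models, " models -> ", x$hidden_units,
      " hidden units -> ", x$n_classes, "-class softmax\n", sep = "")
  invisible(x)
}

#' Predict from a stacking meta-learner
#'
#' @param object a `stacker`.
#' @param stack `M x N x K` prediction array from the same M models.
#' @param ... unused.
#' @return `N x K` probability matrix.
#' @export
predict.stacker <- function(object, stack, ...) {
  check_prediction_set(stack)
  if (dim(stack)[1] != object$n_models) {
    stop("prediction set has the wrong number of models", call. = FALSE)
  }
  x <- do.call(cbind, lapply(seq_len(dim(stack)[1]), function(m) .slice(stack, m)))
  p <- stats::predict(object$fit, x)
  p / rowSums(p)
}

# --------------------------------------------------------------------------
# Bitwise-AND mask fusion

#' Bitwise-AND fusion of binary masks
#'
#' A pixel of the fused mask is foreground only when it is foreground in
#' every input mask (element-wise minimum). The output is therefore a
#' subset of each input; the operation is commutative, associative and
#' idempotent.
#'
#' @param masks list of at least two binary `H x W` matrices.
#' @return fused binary mask.
#' @export
bitwise_and_masks <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L) {
    stop("need at least two masks", call. = FALSE)
  }
  out <- check_binary_mask(masks[[1L]])
  for (m in masks[-1L]) {
    check_binary_mask(m)
    check_same_shape(out, m, "masks")
    out <- pmin(out, m)
  }
  out
}
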