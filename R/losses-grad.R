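# Analytic gradients of the classification losses with respect to
# pre-softmax scores (logits). This is the contract the training engine
# consumes: given a logits batch z, each loss reports its value at
# p = softmax(z) together with dL/dz.
#
# The calibration penalty's correctness indicator and the argmax that
# selects the predicted class are piecewise constant; both are held fixed,
# so gradients flow only through the probability assigned to the predicted
# class. The gradient of the batch confidence term is
#   d conf / d z[i, k] = p[i, j*] * (1[k == j*] - p[i, k]) / N,
# with j* the row argmax. Everything else follows from the softmax Jacobian
#   dL/dz_i = p_i * (g_i - <p_i, g_i>)   with   g_i = dL/dp_i.

.class_loss_spec <- function(name, dots) {
  name <- match.arg(name, .CLASS_LOSSES)
  arg <- function(key, default) dots[[key]] %||% default
  switch(name,
    cce = list(base = "cce", beta = 0, lambda = 0, sigma = 0),
    kl = list(base = "cce", beta = 0, lambda = 0, sigma = 0, kl = TRUE),
    hinge = list(base = "hinge", lambda = 0),
    focal = list(base = "focal", gamma = arg("gamma", 1), lambda = 0, sigma = 0),
    entropy_reg_cce = list(base = "cce", beta = arg("beta", 2), lambda = 0, sigma = 0),
    smoothed_cce = list(base = "cce", beta = 0, lambda = 0, sigma = arg("sigma", 0.2)),
    smoothed_focal = list(base = "focal", gamma = arg("gamma", 1), lambda = 0,
                          sigma = arg("sigma", 0.2)),
    calibrated_cce = list(base = "cce", beta = 0, lambda = arg("lambda_", 10), sigma = 0),
    calibrated_kl = list(base = "cce", beta = 0, lambda = arg("lambda_", 1),
                         sigma = 0, kl = TRUE),
    calibrated_focal = list(base = "focal", gamma = arg("gamma", 1),
                            lambda = arg("lambda_", 1), sigma = 0),
    calibrated_hinge = list(base = "hinge", lambda = arg("lambda_", 10)),
    calibrated_negative_entropy = list(base = "cce", beta = arg("beta", 0.001),
                                       lambda = arg("lambda_", 10), sigma = 0)
  )
}

#' Value and logits-gradient of a registered classification loss
#'
#' Computes the loss at `p = softmax(z)` together with its analytic
#' gradient with respect to the score matrix `z`, under the batch-mean
#' reduction. The correctness indicator and argmax inside the calibration
#' penalty are treated as locally constant.
#'
#' @param name one of [classification_loss_names()].
#' @param y one-hot `N x K` target batch.
#' @param z numeric `N x K` score (logits) matrix.
#' @param ... hyperparameter overrides as in [classification_loss()].
#' @return list with `value` (scalar) and `grad` (`N x K` matrix `dL/dz`).
#' @export
class_loss_grad <- function(name, y, z, ...) {
  spec <- .class_loss_spec(name, list(...))
  if (!is.matrix(z)) stop("z must be a matrix", call. = FALSE)
  check_same_shape(y, z, "targets and scores")
  p <- softmax(z)
  n <- nrow(p)
  value <- classification_loss(name, ...)(y, p)$value

  yy <- if ((spec$sigma %||% 0) > 0) smooth_labels(y, spec$sigma) else y
  pc <- clip_prob(p)

  g <- switch(spec$base,
    cce = {
      out <- -yy / pc
      if (spec$beta != 0) out <- out + spec$beta * (log(pc) + 1)
      out
    },
    focal = {
      gam <- spec$gamma
      pow1 <- if (gam == 0) 0 else gam * (1 - p)^(gam - 1)
      yy * (pow1 * log(pc) - (1 - p)^gam / pc)
    },
    hinge = {
      if (!is_one_hot(y)) {
        stop("hinge gradients require one-hot targets", call. = FALSE)
      }
      pn <- p
      pn[y == 1] <- -Inf
      jstar <- max.col(pn, ties.method = "first")
      margin <- pn[cbind(seq_len(n), jstar)] - rowSums(y * p) + 1
      out <- matrix(0, n, ncol(p))
      active <- margin > 0
      if (any(active)) {
        idx <- which(active)
        out[cbind(idx, jstar[idx])] <- 1
        out[active, ] <- out[active, , drop = FALSE] - y[active, , drop = FALSE]
      }
      out
    }
  )

  inner <- rowSums(p * g)
  grad <- p * (g - inner) / n

  if (spec$lambda > 0) {
    pred <- row_argmax(p)
    truth <- row_argmax(y)
    acc <- mean(pred == truth)
    pj <- p[cbind(seq_len(n), pred + 1L)]
    conf <- mean(pj)
    s <- sign(acc - conf)
    if (s != 0) {
      dconf <- -p * pj / n
      dconf[cbind(seq_len(n), pred + 1L)] <-
        dconf[cbind(seq_len(n), pred + 1L)] + pj / n
      grad <- grad - spec$lambda * s * dconf
    }
  }

  list(value = value, grad = grad)
}
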