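# Binary segmentation losses.
#
# Each loss takes a ground-truth binary mask `gt` (entries exactly 0/1) and
# a predicted soft mask `pred` (foreground probabilities in [0, 1]) of the
# same H x W shape and returns a scalar. Overlap-based losses use soft
# counts TP = sum(g*p), FN = sum(g*(1-p)), FP = sum((1-g)*p) with a
# smoothing constant s = 1 in numerator and denominator so that empty
# masks do not produce 0/0.

#' Binary cross-entropy segmentation loss
#'
#' Pixel-mean of \eqn{-[g \log p + (1-g)\log(1-p)]} with probabilities
#' clipped away from 0 and 1.
#'
#' @param gt binary ground-truth mask (`H x W`, entries 0/1).
#' @param pred predicted soft mask (`H x W`, entries in `[0, 1]`).
#' @return scalar loss.
#' @export
seg_bce <- function(gt, pred) {
  check_binary_mask(gt, "ground-truth mask"); check_soft_mask(pred)
  check_same_shape(gt, pred, "masks")
  pc <- clip_prob(pred)
  mean(-(gt * log(pc) + (1 - gt) * log(1 - pc)))
}

#' Dice segmentation loss
#'
#' \eqn{1 - (2\sum g p + s) / (\sum g + \sum p + s)} with smoothing
#' `s = smooth` (default 1). Zero at a perfect binary prediction.
#'
#' @inheritParams seg_bce
#' @param smooth smoothing constant added to numerator and denominator.
#' @return scalar loss.
#' @export
dice_loss <- function(gt, pred, smooth = 1) {
  check_binary_mask(gt, "ground-truth mask"); check_soft_mask(pred)
  check_same_shape(gt, pred, "masks")
  1 - (2 * sum(gt * pred) + smooth) / (sum(gt) + sum(pred) + smooth)
}

#' Weighted BCE-Dice compound loss
#'
#' `w_bce * seg_bce + (1 - w_bce) * dice_loss`, the usual compromise
#' between a pixel-wise and an overlap-wise criterion.
#'
#' @inheritParams dice_loss
#' @param w_bce BCE weight in `[0, 1]` (default 0.5).
#' @return scalar loss.
#' @export
weighted_bce_dice <- function(gt, pred, w_bce = 0.5) {
  if (!is.numeric(w_bce) || length(w_bce) != 1L || w_bce < 0 || w_bce > 1) {
    stop("w_bce must lie in [0, 1]", call. = FALSE)
  }
  w_bce * seg_bce(gt, pred) + (1 - w_bce) * dice_loss(gt, pred)
}

#' Binary focal segmentation loss
#'
#' Pixel-mean of
#' \eqn{-[g (1-p)^\gamma \log p + (1-g) p^\gamma \log(1-p)]}; reduces to
#' [seg_bce()] at `gamma_f = 0`. No class-balancing prefactor is applied.
#'
#' @inheritParams seg_bce
#' @param gamma_f focusing exponent, `>= 0` (default 2).
#' @return scalar loss.
#' @export
binary_focal <- function(gt, pred, gamma_f = 2) {
  check_binary_mask(gt, "ground-truth mask"); check_soft_mask(pred)
  check_same_shape(gt, pred, "masks")
  if (!is.numeric(gamma_f) || length(gamma_f) != 1L || gamma_f < 0) {
    stop("gamma_f must be >= 0", call. = FALSE)
  }
  pc <- clip_prob(pred)
  mean(-(gt * (1 - pred)^gamma_f * log(pc) +
           (1 - gt) * pred^gamma_f * log(1 - pc)))
}

.tversky_index <- function(gt, pred, alpha, beta_t, smooth) {
  tp <- sum(gt * pred)
  fn <- sum(gt * (1 - pred))
  fp <- sum((1 - gt) * pred)
  (tp + smooth) / (tp + alpha * fn + beta_t * fp + smooth)
}

#' Tversky segmentation loss
#'
#' One minus the soft Tversky index
#' \eqn{(TP + s) / (TP + \alpha FN + \beta FP + s)}. `alpha` weights false
#' negatives and `beta_t` false positives; `alpha = beta_t = 0.5` recovers
#' [dice_loss()] — exactly so for the unsmoothed ratios (`smooth = 0`),
#' and up to a term of order `smooth / area` at the default smoothing,
#' which enters the two ratios differently. Defaults `alpha = 0.7`,
#' `beta_t = 0.3` emphasise recall, the common choice for small
#' foreground structures.
#'
#' @inheritParams dice_loss
#' @param alpha false-negative weight, `>= 0`.
#' @param beta_t false-positive weight, `>= 0`.
#' @return scalar loss.
#' @export
tversky_loss <- function(gt, pred, alpha = 0.7, beta_t = 0.3, smooth = 1) {
  check_binary_mask(gt, "ground-truth mask"); check_soft_mask(pred)
  check_same_shape(gt, pred, "masks")
  if (alpha < 0 || beta_t < 0) stop("alpha and beta_t must be >= 0", call. = FALSE)
  1 - .tversky_index(gt, pred, alpha, beta_t, smooth)
}

#' Focal Tversky segmentation loss
#'
#' \eqn{(1 - TI)^{\gamma_t}} where TI is the soft Tversky index. Exponents
#' below one amplify the gradient near convergence (hard examples);
#' `gamma_t = 1` recovers [tversky_loss()]. Default `gamma_t = 0.75`.
#'
#' @inheritParams tversky_loss
#' @param gamma_t focal exponent, `> 0`.
#' @return scalar loss.
#' @export
focal_tversky_loss <- function(gt, pred, alpha = 0.7, beta_t = 0.3,
                               gamma_t = 0.75, smooth = 1) {
  if (!is.numeric(gamma_t) || length(gamma_t) != 1L || gamma_t <= 0) {
    stop("gamma_t must be > 0", call. = FALSE)
  }
  tversky_loss(gt, pred, alpha, beta_t, smooth)^gamma_t
}

.SEG_LOSSES <- c("bce", "weighted_bce_dice", "focal", "tversky", "focal_tversky")

#' Names of the registered segmentation losses
#' @return character vector of loss names.
#' @export
segmentation_loss_names <- function() .SEG_LOSSES

#' Look up a segmentation loss by name
#'
#' @param name one of [segmentation_loss_names()].
#' @param ... hyperparameter overrides (`w_bce`, `gamma_f`, `alpha`,
#'   `beta_t`, `gamma_t`, `smooth`).
#' @return function `f(gt, pred)` returning a scalar.
#' @export
segmentation_loss <- function(name, ...) {
  name <- match.arg(name, .SEG_LOSSES)
  dots <- list(...)
  arg <- function(key, default) dots[[key]] %||% default
  switch(name,
    bce = seg_bce,
    weighted_bce_dice = {
      w <- arg("w_bce", 0.5)
      function(gt, pred) weighted_bce_dice(gt, pred, w_bce = w)
    },
    focal = {
      g <- arg("gamma_f", 2)
      function(gt, pred) binary_focal(gt, pred, gamma_f = g)
    },
    tversky = {
      a <- arg("alpha", 0.7); b <- arg("beta_t", 0.3); s <- arg("smooth", 1)
      function(gt, pred) tversky_loss(gt, pred, alpha = a, beta_t = b, smooth = s)
    },
    focal_tversky = {
      a <- arg("alpha", 0.7); b <- arg("beta_t", 0.3)
      g <- arg("gamma_t", 0.75); s <- arg("smooth", 1)
      function(gt, pred) {
        focal_tversky_loss(gt, pred, alpha = a, beta_t = b, gamma_t = g, smooth = s)
      }
    }
  )
}

#' Value and logits-gradient of a registered segmentation loss
#'
#' Computes the loss at `p = sigmoid(z)` and its analytic gradient with
#' respect to the pre-sigmoid score map `z`.
#'
#' @param name one of [segmentation_loss_names()].
#' @param gt binary ground-truth mask.
#' @param z numeric score matrix, same shape as `gt`.
#' @param ... hyperparameter overrides as in [segmentation_loss()].
#' @return list with `value` (scalar) and `grad` (matrix `dL/dz`).
#' @export
seg_loss_grad <- function(name, gt, z, ...) {
  name <- match.arg(name, .SEG_LOSSES)
  if (!is.matrix(z)) stop("z must be a matrix", call. = FALSE)
  check_same_shape(gt, z, "mask and scores")
  dots <- list(...)
  arg <- function(key, default) dots[[key]] %||% default
  p <- sigmoid(z)
  npix <- length(p)
  value <- do.call(segmentation_loss, c(list(name = name), dots))(gt, p)
  smooth <- arg("smooth", 1)

  dice_dp <- function() {
    t1 <- 2 * sum(gt * p) + smooth
    t2 <- sum(gt) + sum(p) + smooth
    -(2 * gt * t2 - t1) / t2^2
  }
  tversky_dp <- function(alpha, beta_t) {
    tp <- sum(gt * p)
    d <- tp + alpha * sum(gt * (1 - p)) + beta_t * sum((1 - gt) * p) + smooth
    dd <- gt - alpha * gt + beta_t * (1 - gt)
    -((gt * d - (tp + smooth) * dd) / d^2)
  }

  dLdp <- switch(name,
    bce = (p - gt) / (p * (1 - p)) / npix,
    weighted_bce_dice = {
      w <- arg("w_bce", 0.5)
      w * (p - gt) / (p * (1 - p)) / npix + (1 - w) * dice_dp()
    },
    focal = {
      g <- arg("gamma_f", 2)
      pc <- clip_prob(p)
      pow_fg <- if (g == 0) 0 else g * (1 - p)^(g - 1)
      pow_bg <- if (g == 0) 0 else g * p^(g - 1)
      -(gt * (-pow_fg * log(pc) + (1 - p)^g / pc) +
          (1 - gt) * (pow_bg * log(1 - pc) - p^g / (1 - pc))) / npix
    },
    tversky = tversky_dp(arg("alpha", 0.7), arg("beta_t", 0.3)),
    focal_tversky = {
      a <- arg("alpha", 0.7); b <- arg("beta_t", 0.3); g <- arg("gamma_t", 0.75)
      ti <- .tversky_index(gt, p, a, b, smooth)
      g * (1 - ti)^(g - 1) * tversky_dp(a, b)
    }
  )
  list(value = value, grad = dLdp * p * (1 - p))
}
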