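# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing generators funnel through this, which is what
# makes them bit-reproducible.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Probabilities are clipped to [eps, 1-eps] before any logarithm.
.PROB_EPS <- 1e-7

clip_prob <- function(p, eps = .PROB_EPS) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Validate an N x K probability matrix
#'
#' Checks that `p` is a numeric matrix with entries in `[0, 1]` whose rows
#' sum to one (within `tol`). Returns the matrix invisibly so it can be used
#' inline.
#'
#' @param p numeric matrix, one row per sample, one column per class.
#' @param tol allowed deviation of each row sum from 1.
#' @return `p`, invisibly.
#' @export
check_prob_batch <- function(p, tol = 1e-6) {
  if (!is.matrix(p) || !is.numeric(p)) {
    stop("probability batch must be a numeric matrix", call. = FALSE)
  }
  if (nrow(p) < 1L || ncol(p) < 2L) {
    stop("probability batch needs N >= 1 rows and K >= 2 columns", call. = FALSE)
  }
  if (anyNA(p) || any(p < -tol) || any(p > 1 + tol)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(p)
  if (any(abs(rs - 1) > tol)) {
    stop("every probability row must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  invisible(p)
}

check_target_batch <- function(y, tol = 1e-6) {
  check_prob_batch(y, tol = tol)
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(what, " must have identical dimensions", call. = FALSE)
  }
  invisible(NULL)
}

is_one_hot <- function(y, tol = 1e-6) {
  is.matrix(y) &&
    all(abs(y) < tol | abs(y - 1) < tol) &&
    all(abs(rowSums(y) - 1) < tol)
}

check_binary_mask <- function(m, what = "mask") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (!all(m %in% c(0, 1))) {
    stop(what, " must contain only 0 and 1", call. = FALSE)
  }
  invisible(m)
}

check_soft_mask <- function(m, what = "predicted mask") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(m) || any(m < 0) || any(m > 1)) {
    stop(what, " entries must lie in [0, 1]", call. = FALSE)
  }
  invisible(m)
}

#' One-hot encode integer class labels
#'
#' Labels are 0-based class indices (`0, ..., K-1`), matching the class
#' coding used throughout the package (0 = bacterial-like, 1 = normal,
#' 2 = viral-like for the synthetic three-class task).
#'
#' @param labels integer vector of 0-based class indices.
#' @param n_classes number of classes `K`; defaults to `max(labels) + 1`.
#' @return an `N x K` one-hot matrix.
#' @export
one_hot <- function(labels, n_classes = NULL) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("labels must be non-empty", call. = FALSE)
  K <- as.integer(n_classes %||% (max(labels) + 1L))
  if (any(labels < 0L) || any(labels >= K)) {
    stop("labels must lie in [0, ", K, ")", call. = FALSE)
  }
  y <- matrix(0, nrow = length(labels), ncol = K)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

#' Row-wise softmax
#'
#' Numerically stable softmax over the rows of a score matrix.
#'
#' @param z numeric matrix of scores (logits), one row per sample.
#' @return matrix of the same shape with rows on the probability simplex.
#' @export
softmax <- function(z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  zm <- z - apply(z, 1L, max)
  e <- exp(zm)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# 0-based argmax per row, ties broken toward the lowest class index.
row_argmax <- function(p) {
  max.col(p, ties.method = "first") - 1L
}
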