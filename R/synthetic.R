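# Seeded synthetic-data generators. These replace external chest-radiograph
# datasets with controllable stand-ins: class-imbalanced label vectors,
# prediction matrices with prescribed accuracy and confidence (so the
# calibration gap of a generated batch is known by construction), correlated
# model zoos, and toy image/mask pairs with two elliptical "lungs" and
# class-specific opacity patterns (focal blob = class 0 "bacterial-like",
# clean = class 1 "normal", diffuse streaks = class 2 "viral-like").

check_labels <- function(labels, n_classes = NULL) {
  labels <- as.integer(labels)
  if (length(labels) < 1L) stop("labels must be non-empty", call. = FALSE)
  K <- as.integer(n_classes %||% (max(labels) + 1L))
  if (K < 2L) stop("need at least two classes", call. = FALSE)
  if (any(labels < 0L) || any(labels >= K)) {
    stop("labels must lie in [0, ", K, ")", call. = FALSE)
  }
  labels
}

#' Generate class labels from sampling probabilities
#'
#' Draws `n_samples` 0-based class indices i.i.d. from `class_probs`.
#' Identical seeds give identical outputs.
#'
#' @param n_samples number of labels, `>= 1`.
#' @param class_probs length-`K` vector of non-negative sampling
#'   probabilities summing to 1.
#' @param seed integer RNG seed.
#' @return integer vector of 0-based class indices.
#' @export
gen_labels <- function(n_samples, class_probs, seed) {
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop("n_samples must be >= 1", call. = FALSE)
  }
  if (!is.numeric(class_probs) || length(class_probs) < 2L ||
      any(class_probs < 0) || abs(sum(class_probs) - 1) > 1e-9) {
    stop("class_probs must be non-negative and sum to 1", call. = FALSE)
  }
  with_seed(seed, {
    sample.int(length(class_probs), size = n_samples, replace = TRUE,
               prob = class_probs) - 1L
  })
}

# Draw an argmax probability with mean `conf` (Beta with concentration
# `nu`), clamped so it stays a valid argmax value above 1/K.
.draw_conf <- function(u, conf, K, nu = 50) {
  if (conf >= 1 - 1e-9) return(rep(1, length(u)))
  c0 <- stats::qbeta(u, conf * nu, (1 - conf) * nu)
  pmin(pmax(c0, 1 / K + 1e-3), 1 - 1e-6)
}

# Fill one probability row: argmax class `j` (0-based) gets `cj`, the
# remainder is split over the other classes with random proportions, or
# equally if a random split would overtake the argmax.
.fill_rows <- function(n, K, j, cj, split) {
  p <- matrix(0, n, K)
  rest <- 1 - cj
  w <- split / rowSums(split)              # n x (K-1) proportions
  bad <- apply(w, 1L, max) * rest >= cj - 1e-9
  if (any(bad)) w[bad, ] <- 1 / (K - 1)
  others <- w * rest
  for (i in seq_len(n)) {
    cols <- setdiff(seq_len(K), j[i] + 1L)
    p[i, cols] <- others[i, ]
    p[i, j[i] + 1L] <- cj[i]
  }
  p
}

#' Generate a prediction batch with controlled accuracy and confidence
#'
#' Builds an `N x K` probability matrix whose realized top-1 accuracy
#' equals `target_accuracy` up to rounding (exactly
#' `round(N * target_accuracy)` rows have their argmax on the true label;
#' the correct rows are a seeded random subset) and whose mean argmax
#' probability concentrates at `target_confidence` (Beta draws with that
#' mean). The batch calibration gap is therefore
#' `|target_accuracy - target_confidence|` up to Monte-Carlo noise of a
#' few thousandths at `N = 2000`.
#'
#' @param labels 0-based class-index vector (the true classes).
#' @param target_accuracy fraction in `[0, 1]`.
#' @param target_confidence mean argmax probability, in `(1/K, 1]`.
#' @param seed integer RNG seed.
#' @param n_classes number of classes `K`; defaults to `max(labels) + 1`.
#' @return `N x K` probability matrix.
#' @export
gen_prediction_batch <- function(labels, target_accuracy, target_confidence,
                                 seed, n_classes = NULL) {
  labels <- check_labels(labels, n_classes)
  K <- as.integer(n_classes %||% (max(labels) + 1L))
  n <- length(labels)
  if (target_accuracy < 0 || target_accuracy > 1) {
    stop("target_accuracy must lie in [0, 1]", call. = FALSE)
  }
  if (target_confidence < 1 / K + 1e-9 || target_confidence > 1) {
    stop("target_confidence must lie in (1/K, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n_correct <- round(n * target_accuracy)
    correct <- logical(n)
    correct[sample.int(n, n_correct)] <- TRUE
    j <- labels
    wrong <- which(!correct)
    if (length(wrong)) {
      shift <- sample.int(K - 1L, length(wrong), replace = TRUE)
      j[wrong] <- (labels[wrong] + shift) %% K
    }
    cj <- .draw_conf(stats::runif(n), target_confidence, K)
    split <- matrix(stats::rgamma(n * (K - 1L), shape = 3), n, K - 1L)
    .fill_rows(n, K, j, cj, split)
  })
}

#' Generate a zoo of correlated prediction models
#'
#' Produces an `M x N x K` stack of probability matrices. Each model `m`
#' has realized accuracy close to `per_model_accuracy[m]` (stratified
#' correctness draws). The `agreement` knob sets the fraction of rows for
#' which all models reuse one shared random draw (so their errors and
#' confidences coincide); with `agreement = 1` and equal accuracies all
#' slices are identical.
#'
#' @param labels 0-based class-index vector.
#' @param per_model_accuracy length-`M` vector of accuracies in `[0, 1]`.
#' @param agreement fraction of shared rows in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param per_model_confidence optional length-`M` mean argmax
#'   probabilities; defaults to `max(accuracy, 1/K + 0.05)` per model
#'   (calibrated models).
#' @param n_classes number of classes `K`.
#' @return `M x N x K` array; `dimnames[[1]]` carries model ids.
#' @export
gen_model_zoo <- function(labels, per_model_accuracy, agreement, seed,
                          per_model_confidence = NULL, n_classes = NULL) {
  labels <- check_labels(labels, n_classes)
  K <- as.integer(n_classes %||% (max(labels) + 1L))
  M <- length(per_model_accuracy)
  if (M < 1L) stop("the zoo must contain at least one model", call. = FALSE)
  if (any(per_model_accuracy < 0) || any(per_model_accuracy > 1)) {
    stop("accuracies must lie in [0, 1]", call. = FALSE)
  }
  if (agreement < 0 || agreement > 1) {
    stop("agreement must lie in [0, 1]", call. = FALSE)
  }
  n <- length(labels)
  conf <- per_model_confidence %||% pmax(per_model_accuracy, 1 / K + 0.05)
  if (length(conf) != M) {
    stop("per_model_confidence must have one entry per model", call. = FALSE)
  }
  with_seed(seed, {
    grid <- (seq_len(n) - 0.5) / n
    u_shared <- sample(grid)
    v_shared <- stats::runif(n)
    w_shared <- sample.int(K - 1L, n, replace = TRUE)
    s_shared <- matrix(stats::rgamma(n * (K - 1L), shape = 3), n, K - 1L)
    shared_rows <- logical(n)
    shared_rows[sample.int(n, round(agreement * n))] <- TRUE

    stack <- array(0, dim = c(M, n, K),
                   dimnames = list(paste0("model_", seq_len(M)), NULL, NULL))
    for (m in seq_len(M)) {
      u <- sample(grid); v <- stats::runif(n)
      wcls <- sample.int(K - 1L, n, replace = TRUE)
      spl <- matrix(stats::rgamma(n * (K - 1L), shape = 3), n, K - 1L)
      u[shared_rows] <- u_shared[shared_rows]
      v[shared_rows] <- v_shared[shared_rows]
      wcls[shared_rows] <- w_shared[shared_rows]
      spl[shared_rows, ] <- s_shared[shared_rows, , drop = FALSE]

      correct <- u < per_model_accuracy[m]
      j <- labels
      j[!correct] <- (labels[!correct] + wcls[!correct]) %% K
      cj <- .draw_conf(v, conf[m], K)
      stack[m, , ] <- .fill_rows(n, K, j, cj, spl)
    }
    stack
  })
}

# --------------------------------------------------------------------------
# Toy images

.ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

.add_streak <- function(h, w, cy, cx, angle, len, width, amp) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  along <- dy * cos(angle) + dx * sin(angle)
  across <- -dy * sin(angle) + dx * cos(angle)
  amp * (abs(along) <= len / 2) * exp(-(across / width)^2 / 2)
}

#' Generate one synthetic chest-image/mask/label sample
#'
#' Builds an `height x width` grayscale image in `[0, 1]` with two
#' elliptical "lung" regions (the binary mask) over a noisy background
#' (Gaussian noise, sd 0.05). Class-specific structure is added strictly
#' inside the mask: class 0 receives one bright focal blob in a single
#' lung, class 2 receives at least four low-contrast streaks spread over
#' both lungs, class 1 receives none. Deterministic per seed.
#'
#' @param class_label 0, 1 or 2.
#' @param height,width image size in pixels, `>= 32`.
#' @param seed integer RNG seed.
#' @return list with `image` (matrix in `[0,1]`), `mask` (0/1 matrix) and
#'   `label`.
#' @export
gen_sample <- function(class_label, height = 64, width = 64, seed = 1) {
  if (!class_label %in% c(0, 1, 2)) {
    stop("class_label must be 0, 1 or 2", call. = FALSE)
  }
  if (height < 32 || width < 32) {
    stop("height and width must be >= 32", call. = FALSE)
  }
  with_seed(seed, {
    h <- as.integer(height); w <- as.integer(width)
    jit <- function(s) stats::runif(1, -s, s)
    cy <- (0.52 + jit(0.02)) * h
    ry <- (0.28 + jit(0.02)) * h
    rx <- (0.13 + jit(0.01)) * w
    cx1 <- (0.28 + jit(0.015)) * w
    cx2 <- (0.72 + jit(0.015)) * w
    e1 <- .ellipse_mask(h, w, cy, cx1, ry, rx)
    e2 <- .ellipse_mask(h, w, cy, cx2, ry, rx)
    mask <- (e1 | e2) * 1

    img <- matrix(stats::rnorm(h * w, mean = 0.2, sd = 0.05), h, w)
    img <- img + 0.4 * mask

    if (class_label == 0) {
      lung <- if (stats::runif(1) < 0.5) list(cy = cy, cx = cx1) else list(cy = cy, cx = cx2)
      by <- lung$cy + jit(0.4) * ry
      bx <- lung$cx + jit(0.4) * rx
      sig <- 0.09 * min(h, w)
      yy <- matrix(seq_len(h), h, w)
      xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      blob <- 0.35 * exp(-(((yy - by)^2 + (xx - bx)^2) / (2 * sig^2)))
      img <- img + blob * mask
    } else if (class_label == 2) {
      per_lung <- sample(2:3, 1)
      for (cx in c(cx1, cx2)) {
        for (s in seq_len(per_lung)) {
          sy <- cy + jit(0.6) * ry
          sx <- cx + jit(0.5) * rx
          ang <- stats::runif(1, -0.5, 0.5)     # roughly vertical streaks
          len <- stats::runif(1, 0.8, 1.4) * ry
          img <- img + .add_streak(h, w, sy, sx, ang, len,
                                   width = 0.9, amp = 0.13) * mask
        }
      }
    }
    list(image = pmin(pmax(img, 0), 1), mask = mask, label = as.integer(class_label))
  })
}

#' Generate a batch of synthetic samples as arrays
#'
#' Convenience wrapper around [gen_sample()]: one sample per label, with
#' per-sample seeds derived from `seed`.
#'
#' @param labels 0-based class-index vector.
#' @param height,width image size.
#' @param seed integer RNG seed.
#' @return list with `x` (`N x H x W x 1` image array), `masks`
#'   (`N x H x W` array) and `labels`.
#' @export
gen_samples <- function(labels, height = 64, width = 64, seed = 1) {
  labels <- check_labels(labels, 3L)
  n <- length(labels)
  offsets <- with_seed(seed, sample.int(2^30, n))
  x <- array(0, dim = c(n, height, width, 1L))
  masks <- array(0, dim = c(n, height, width))
  for (i in seq_len(n)) {
    s <- gen_sample(labels[i], height, width, seed = offsets[i])
    x[i, , , 1L] <- s$image
    masks[i, , ] <- s$mask
  }
  list(x = x, masks = masks, labels = labels)
}

# --------------------------------------------------------------------------
# Plain-text / PNG external interfaces

#' Write synthetic samples as PNG pairs plus a CSV manifest
#'
#' @param dataset result of [gen_samples()].
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_samples <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$labels)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ip <- file.path(dir, sprintf("sample_%04d.png", i))
    mp <- file.path(dir, sprintf("mask_%04d.png", i))
    png::writePNG(dataset$x[i, , , 1L], ip)
    png::writePNG(dataset$masks[i, , ], mp)
    rows[[i]] <- data.frame(path = ip, mask_path = mp,
                            label = dataset$labels[i])
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read an 8-bit grayscale PNG as a matrix in `[0, 1]`
#'
#' @param path PNG path.
#' @return numeric matrix.
#' @export
read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Write a prediction set and labels as CSV files
#'
#' One `model_<id>.csv` per model (N rows, K probability columns) plus a
#' `labels.csv` with the 0-based true classes.
#'
#' @param stack `M x N x K` prediction array (see [gen_model_zoo()]).
#' @param labels 0-based class-index vector.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_prediction_set <- function(stack, labels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- dimnames(stack)[[1]] %||% paste0("model_", seq_len(dim(stack)[1]))
  for (m in seq_len(dim(stack)[1])) {
    pm <- stack[m, , , drop = TRUE]
    colnames(pm) <- paste0("class_", seq_len(ncol(pm)) - 1L)
    utils::write.csv(pm, file.path(dir, paste0(ids[m], ".csv")), row.names = FALSE)
  }
  utils::write.csv(data.frame(label = labels), file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a prediction set written by [write_prediction_set()]
#'
#' @param dir directory containing `model_*.csv` and `labels.csv`.
#' @return list with `stack` (`M x N x K` array) and `labels`.
#' @export
read_prediction_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "^model_.*\\.csv$", full.names = TRUE))
  if (length(files) < 1L) stop("no model_*.csv files in ", dir, call. = FALSE)
  mats <- lapply(files, function(f) as.matrix(utils::read.csv(f)))
  M <- length(mats)
  stack <- array(0, dim = c(M, nrow(mats[[1]]), ncol(mats[[1]])),
                 dimnames = list(sub("\\.csv$", "", basename(files)), NULL, NULL))
  for (m in seq_len(M)) stack[m, , ] <- mats[[m]]
  labels <- utils::read.csv(file.path(dir, "labels.csv"))$label
  list(stack = stack, labels = as.integer(labels))
}
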