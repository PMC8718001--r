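# Network assembly and training contracts: the encoder-decoder segmenter
# with skip connections, encoder truncation for modality-specific
# transfer, the classifier head (zero-padding -> 3x3 convolution -> global
# average pooling -> softmax dense), the model-level feature-fusion head,
# and a training loop with a fixed-seed validation split, plateau learning
# rate reduction and best-checkpoint selection.

#' Backbone specification
#'
#' The `tiny` backbone is a three-stage convolutional encoder (default
#' widths 8/16/32, under 50k parameters end to end) used by every test
#' and example in this package; its truncation point is the deepest
#' encoder stage `"stage3"`, whose feature map is `(H/4, W/4, widths[3])`.
#' Larger pretrained encoders can be plugged in by supplying a spec with
#' more stages/widths; nothing in the training contracts depends on the
#' tiny scale.
#'
#' @param name backbone identifier (only `"tiny"` ships with the package).
#' @param widths per-stage channel widths.
#' @return list of class `backbone_spec`.
#' @export
backbone_spec <- function(name = "tiny", widths = c(8L, 16L, 32L)) {
  if (!identical(name, "tiny")) {
    stop("unknown backbone '", name, "'; supply widths for a custom spec ",
         "via backbone_spec('tiny', widths = ...)", call. = FALSE)
  }
  if (length(widths) != 3L || any(widths < 1L)) {
    stop("tiny backbone needs three positive stage widths", call. = FALSE)
  }
  structure(list(name = name, widths = as.integer(widths),
                 stages = c("stage1", "stage2", "stage3"),
                 truncation_point = "stage3"),
            class = "backbone_spec")
}

.encoder_layers <- function(bb) {
  w <- bb$widths
  list(
    list(op = "conv", name = "enc1", k = 3L, filters = w[1], pad = 1L,
         act = "lrelu", tap = "stage1"),
    list(op = "pool2"),
    list(op = "conv", name = "enc2", k = 3L, filters = w[2], pad = 1L,
         act = "lrelu", tap = "stage2"),
    list(op = "pool2"),
    list(op = "conv", name = "enc3", k = 3L, filters = w[3], pad = 1L,
         act = "lrelu", tap = "stage3")
  )
}

#' Build an encoder-decoder segmentation network
#'
#' U-style network: the backbone encoder (two 2x2 max-pool reductions),
#' a symmetric decoder with nearest-neighbour upsampling and skip
#' connections from the matching encoder stages, and a single-channel
#' 1x1-convolution output head. The network outputs pre-sigmoid scores;
#' [predict.calens_net()] applies the sigmoid.
#'
#' @param backbone a [backbone_spec()].
#' @param input_shape `c(H, W, C)`; H and W must be divisible by 4.
#' @param seed integer seed for weight initialization.
#' @return a `calens_net` of kind `"segmenter"`.
#' @export
build_segmenter <- function(backbone = backbone_spec(),
                            input_shape = c(32L, 32L, 1L), seed = 1) {
  if (!inherits(backbone, "backbone_spec")) {
    stop("backbone must be a backbone_spec()", call. = FALSE)
  }
  w <- backbone$widths
  layers <- c(.encoder_layers(backbone), list(
    list(op = "up2"),
    list(op = "concat", with = "stage2"),
    list(op = "conv", name = "dec2", k = 3L, filters = w[2], pad = 1L, act = "lrelu"),
    list(op = "up2"),
    list(op = "concat", with = "stage1"),
    list(op = "conv", name = "dec1", k = 3L, filters = w[1], pad = 1L, act = "lrelu"),
    list(op = "conv", name = "seg_out", k = 1L, filters = 1L, pad = 0L,
         act = "linear")
  ))
  new_network(layers, as.integer(input_shape), kind = "segmenter", seed = seed)
}

#' Truncate a network at a named encoder stage
#'
#' Returns the sub-network up to (and including) the layer tapped with
#' `point`. The extractor shares its parameter environment with the
#' parent: training either network mutates the shared weights, which is
#' the mechanism behind modality-specific transfer from a trained
#' segmenter to a classifier.
#'
#' @param net a `calens_net` (typically a trained segmenter).
#' @param point tap name of an encoder stage (default `"stage3"`).
#' @return a `calens_net` of kind `"extractor"`.
#' @export
truncate_encoder <- function(net, point = "stage3") {
  taps <- vapply(net$layers, function(ly) ly$tap %||% "", character(1))
  i <- match(point, taps)
  if (is.na(i)) stop("no encoder stage tapped '", point, "'", call. = FALSE)
  structure(list(layers = net$layers[seq_len(i)],
                 input_shape = net$input_shape, kind = "extractor",
                 params = net$params),
            class = "calens_net")
}

#' Append a classification head to a feature extractor
#'
#' Head structure: zero padding (width 1) -> 3x3 convolution (`conv_filters`
#' filters, default the extractor's output width, i.e. the full-scale 512
#' scaled proportionally) -> global average pooling -> dense layer with
#' `n_classes` units. The 3x3 convolution output is tapped as `"dcl"`
#' (deepest convolutional layer) for model-level feature fusion. The head
#' shares the extractor's parameter environment, so training the
#' classifier fine-tunes the (possibly segmentation-pretrained) encoder.
#' Use [clone_network()] on the extractor first to train from an
#' independent copy.
#'
#' @param extractor a `calens_net` from [truncate_encoder()], or a full
#'   encoder built elsewhere.
#' @param n_classes output classes (default 3).
#' @param conv_filters head convolution width; `NULL` keeps the
#'   extractor's output width.
#' @param seed integer seed for head weight initialization.
#' @return a `calens_net` of kind `"classifier"` producing logits.
#' @export
build_classifier <- function(extractor, n_classes = 3L, conv_filters = NULL,
                             seed = 1) {
  feat_shape <- extractor$layers[[length(extractor$layers)]]$out_shape
  if (length(feat_shape) != 3L) {
    stop("extractor must end in a spatial feature map", call. = FALSE)
  }
  conv_filters <- as.integer(conv_filters %||% feat_shape[3])
  layers <- c(extractor$layers, list(
    list(op = "zeropad", p = 1L),
    list(op = "conv", name = "head_conv", k = 3L, filters = conv_filters,
         pad = 0L, act = "lrelu", tap = "dcl"),
    list(op = "gap"),
    list(op = "dense", name = "head_dense", units = as.integer(n_classes))
  ))
  new_network(layers, extractor$input_shape, kind = "classifier", seed = seed,
              params = extractor$params)
}

#' Extract feature maps at a tapped layer
#'
#' @param net a `calens_net`.
#' @param x input array `N x H x W x C`.
#' @param point tap name (default `"dcl"`).
#' @param batch_size forward mini-batch size.
#' @return `N x h x w x c` feature array.
#' @export
extract_features <- function(net, x, point = "dcl", batch_size = 64L) {
  taps <- vapply(net$layers, function(ly) ly$tap %||% "", character(1))
  if (!point %in% taps) stop("no tap named '", point, "'", call. = FALSE)
  N <- dim(x)[1]
  outs <- vector("list", ceiling(N / batch_size))
  for (bi in seq_along(outs)) {
    rows <- ((bi - 1L) * batch_size + 1L):min(bi * batch_size, N)
    fw <- .net_forward(net, x[rows, , , , drop = FALSE], tap_stop = point)
    outs[[bi]] <- fw$taps[[point]]
  }
  d1 <- dim(outs[[1]])
  out <- array(0, c(N, d1[2], d1[3], d1[4]))
  at <- 1L
  for (o in outs) {
    n <- dim(o)[1]
    out[at:(at + n - 1L), , , ] <- o
    at <- at + n
  }
  out
}

#' Concatenate per-model feature stacks along channels
#'
#' @param stacks list of `N x h x w x c` arrays with identical shapes.
#' @return `N x h x w x (M c)` array.
#' @export
concat_features <- function(stacks) {
  if (!is.list(stacks) || length(stacks) < 2L) {
    stop("need at least two feature stacks", call. = FALSE)
  }
  d <- dim(stacks[[1]])
  for (s in stacks[-1]) {
    if (!identical(dim(s)[1:3], d[1:3])) {
      stop("feature stacks must share N x h x w shape", call. = FALSE)
    }
  }
  channels <- vapply(stacks, function(s) dim(s)[4], numeric(1))
  out <- array(0, c(d[1], d[2], d[3], sum(channels)))
  at <- 0L
  for (s in stacks) {
    out[, , , at + seq_len(dim(s)[4])] <- s
    at <- at + dim(s)[4]
  }
  out
}

#' Build a feature-fusion classification head
#'
#' The model-level ensemble head: channel concatenation of the constituent
#' models' deepest convolutional feature maps (done by
#' [concat_features()]), a 1x1 convolution reducing to `fused_channels`,
#' global average pooling and a `n_classes`-unit dense layer. Only the
#' head is trainable; the constituent extractors are frozen by
#' construction since the head consumes precomputed features.
#'
#' @param stacks list of `N x h x w x c` feature arrays (used for shape
#'   inference only).
#' @param fused_channels 1x1-convolution output width; `NULL` keeps one
#'   constituent's width (the full-scale 1536 -> 512 reduction, scaled).
#' @param n_classes output classes.
#' @param seed integer seed.
#' @return a `calens_net` of kind `"classifier"` taking the concatenated
#'   feature array as input.
#' @export
fuse_features <- function(stacks, fused_channels = NULL, n_classes = 3L,
                          seed = 1) {
  d <- dim(stacks[[1]])
  for (s in stacks[-1]) {
    if (!identical(dim(s)[1:3], d[1:3])) {
      stop("feature stacks must share N x h x w shape", call. = FALSE)
    }
  }
  total_c <- sum(vapply(stacks, function(s) dim(s)[4], numeric(1)))
  fused_channels <- as.integer(fused_channels %||% dim(stacks[[1]])[4])
  if (fused_channels < 1L) stop("fused_channels must be >= 1", call. = FALSE)
  layers <- list(
    list(op = "conv", name = "fuse_conv", k = 1L, filters = fused_channels,
         pad = 0L, act = "lrelu", tap = "fused"),
    list(op = "gap"),
    list(op = "dense", name = "fuse_dense", units = as.integer(n_classes))
  )
  new_network(layers, c(d[2], d[3], total_c), kind = "classifier", seed = seed)
}

# --------------------------------------------------------------------------
# Training loop

#' Training configuration
#'
#' Defaults mirror the protocols used for the full-scale task: SGD with
#' initial learning rate 1e-3 and momentum 0.9 for classification, Adam
#' with learning rate 1e-3 for segmentation (pass `optimizer = "adam"`),
#' a fixed-seed 10% validation split, and learning-rate reduction by
#' `lr_factor` whenever the validation loss fails to improve for
#' `patience` epochs. Epoch budget, patience and factor are package
#' defaults (50 / 5 / 0.5); the batch size (default 32) also sets the
#' mini-batch over which the calibration gap of calibrated losses is
#' computed.
#'
#' @param loss_name registered loss name ([classification_loss_names()] or
#'   [segmentation_loss_names()], depending on the network kind).
#' @param optimizer `"sgd"` or `"adam"`.
#' @param lr initial learning rate, `> 0`.
#' @param momentum SGD momentum.
#' @param val_fraction validation fraction in `(0, 1)`.
#' @param patience epochs without improvement before LR reduction.
#' @param lr_factor multiplicative LR reduction in `(0, 1)`.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param seed integer seed controlling split, shuffling and augmentation.
#' @param loss_args named list of loss hyperparameter overrides.
#' @param augment optional [augment_spec()] applied to segmentation
#'   mini-batches.
#' @param verbose print per-epoch losses?
#' @return list of class `train_config`.
#' @export
train_config <- function(loss_name, optimizer = c("sgd", "adam"), lr = 1e-3,
                         momentum = 0.9, val_fraction = 0.1, patience = 5L,
                         lr_factor = 0.5, epochs = 50L, batch_size = 32L,
                         seed = 1L, loss_args = list(), augment = NULL,
                         verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  if (lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (lr_factor <= 0 || lr_factor >= 1) {
    stop("lr_factor must lie in (0, 1)", call. = FALSE)
  }
  structure(list(loss_name = loss_name, optimizer = optimizer, lr = lr,
                 momentum = momentum, val_fraction = val_fraction,
                 patience = as.integer(patience), lr_factor = lr_factor,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss_args = loss_args,
                 augment = augment, verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Read a training configuration from YAML
#'
#' @param path YAML file whose fields mirror [train_config()].
#' @return a `train_config`.
#' @export
train_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  }
  do.call(train_config, yaml::read_yaml(path))
}

.batch_loss_grad <- function(net, xb, yb, cfg, n_classes) {
  fw <- .net_forward(net, xb, want_cache = TRUE)
  z <- fw$out
  if (net$kind == "segmenter") {
    n <- dim(xb)[1]
    value <- 0
    dz <- array(0, dim(z))
    for (i in seq_len(n)) {
      zi <- matrix(z[i, , , 1L], dim(z)[2], dim(z)[3])
      gi <- matrix(yb[i, , ], dim(z)[2], dim(z)[3])
      sg <- do.call(seg_loss_grad,
                    c(list(name = cfg$loss_name, gt = gi, z = zi), cfg$loss_args))
      value <- value + sg$value / n
      dz[i, , , 1L] <- sg$grad / n
    }
    list(fw = fw, value = value, grad = dz)
  } else {
    lg <- do.call(class_loss_grad,
                  c(list(name = cfg$loss_name, y = one_hot(yb, n_classes), z = z),
                    cfg$loss_args))
    list(fw = fw, value = lg$value, grad = lg$grad)
  }
}

.eval_loss <- function(net, x, y, cfg, n_classes, batch_size = 64L) {
  if (net$kind == "segmenter") {
    N <- dim(x)[1]
    total <- 0
    lossfn <- do.call(segmentation_loss,
                      c(list(name = cfg$loss_name), cfg$loss_args))
    p <- predict(net, x, batch_size = batch_size)
    for (i in seq_len(N)) {
      total <- total + lossfn(matrix(y[i, , ], dim(x)[2], dim(x)[3]),
                              matrix(p[i, , ], dim(x)[2], dim(x)[3])) / N
    }
    total
  } else {
    p <- predict(net, x, batch_size = batch_size)
    lossfn <- do.call(classification_loss,
                      c(list(name = cfg$loss_name), cfg$loss_args))
    lossfn(one_hot(y, n_classes), p)$value
  }
}

.augment_batch <- function(xb, yb, spec) {
  n <- dim(xb)[1]
  for (i in seq_len(n)) {
    dy <- sample(seq(-spec$max_shift_px, spec$max_shift_px), 1L)
    dx <- sample(seq(-spec$max_shift_px, spec$max_shift_px), 1L)
    flip <- spec$hflip && stats::runif(1) < 0.5
    ang <- stats::runif(1, -spec$max_rotation_deg, spec$max_rotation_deg)
    tr <- apply_affine(matrix(xb[i, , , 1L], dim(xb)[2], dim(xb)[3]),
                       matrix(yb[i, , ], dim(xb)[2], dim(xb)[3]),
                       dy = dy, dx = dx, flip = flip, angle_deg = ang)
    xb[i, , , 1L] <- tr$image
    yb[i, , ] <- tr$mask
  }
  list(x = xb, y = yb)
}

#' Train a network
#'
#' Splits off `val_fraction` of the data with the configured seed, trains
#' with mini-batch gradient descent on the configured loss (classification
#' losses receive logits, segmentation losses pre-sigmoid score maps),
#' reduces the learning rate by `lr_factor` after `patience` epochs
#' without validation-loss improvement, and restores the parameters of
#' the epoch with the least validation loss before returning. Aborts with
#' diagnostics if the loss becomes non-finite. Fully deterministic given
#' (seed, data, config).
#'
#' @param net a `calens_net` (classifier or segmenter). Trained in place
#'   (parameters live in an environment) and also returned.
#' @param x input array `N x H x W x C`.
#' @param y 0-based class labels (classifier) or `N x H x W` binary mask
#'   array (segmenter).
#' @param cfg a [train_config()].
#' @param n_classes number of classes for classifiers.
#' @param trainable optional character vector of parameter-layer names to
#'   update (e.g. `c("head_conv", "head_dense")` to train a classifier
#'   head on a frozen encoder); `NULL` trains everything.
#' @return list of class `calens_fit`: `net`, `history` (data frame with
#'   epoch, train_loss, val_loss, lr), `best_epoch`, `config`.
#' @export
train <- function(net, x, y, cfg, n_classes = 3L, trainable = NULL) {
  if (!inherits(cfg, "train_config")) stop("cfg must be a train_config()", call. = FALSE)
  N <- dim(x)[1]
  if (N < 2L) stop("need at least two samples", call. = FALSE)
  is_seg <- net$kind == "segmenter"
  if (is_seg && length(dim(y)) != 3L) {
    stop("segmenter training needs an N x H x W mask array", call. = FALSE)
  }
  if (!is_seg && length(y) != N) {
    stop("label count must match sample count", call. = FALSE)
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  best <- list(val = Inf, epoch = 0L, snap = NULL)

  with_seed(cfg$seed, {
    n_val <- max(1L, round(cfg$val_fraction * N))
    val_idx <- sample.int(N, n_val)
    tr_idx <- setdiff(seq_len(N), val_idx)
    x_tr <- x[tr_idx, , , , drop = FALSE]
    x_val <- x[val_idx, , , , drop = FALSE]
    if (is_seg) {
      y_tr <- y[tr_idx, , , drop = FALSE]
      y_val <- y[val_idx, , , drop = FALSE]
    } else {
      y_tr <- y[tr_idx]; y_val <- y[val_idx]
    }

    st <- .opt_init(net)
    lr <- cfg$lr
    stall <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(seq_along(tr_idx))
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, length(ord), cfg$batch_size)) {
        rows <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        xb <- x_tr[rows, , , , drop = FALSE]
        yb <- if (is_seg) y_tr[rows, , , drop = FALSE] else y_tr[rows]
        if (is_seg && !is.null(cfg$augment)) {
          ab <- .augment_batch(xb, yb, cfg$augment)
          xb <- ab$x; yb <- ab$y
        }
        bl <- .batch_loss_grad(net, xb, yb, cfg, n_classes)
        if (!is.finite(bl$value)) {
          stop("non-finite training loss at epoch ", epoch,
               " (lr = ", lr, ", loss = ", cfg$loss_name, ")", call. = FALSE)
        }
        grads <- .net_backward(net, bl$fw, bl$grad)
        if (!is.null(trainable)) grads <- grads[intersect(names(grads), trainable)]
        .opt_step(net, grads, st, cfg$optimizer, lr, cfg$momentum)
        epoch_loss <- epoch_loss + bl$value
        n_batches <- n_batches + 1L
      }
      val_loss <- .eval_loss(net, x_val, y_val, cfg, n_classes)
      history[epoch, ] <- list(epoch, epoch_loss / n_batches, val_loss, lr)
      if (cfg$verbose) {
        cat(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e\n",
                    epoch, epoch_loss / n_batches, val_loss, lr))
      }
      if (val_loss < best$val - 1e-8) {
        best$val <- val_loss; best$epoch <- epoch
        best$snap <- .snapshot_params(net)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) {
          lr <- lr * cfg$lr_factor
          stall <- 0L
        }
      }
    }
  })

  if (!is.null(best$snap)) .restore_params(net, best$snap)
  structure(list(net = net, history = history, best_epoch = best$epoch,
                 config = cfg),
            class = "calens_fit")
}

#' @export
print.calens_fit <- function(x, ...) {
  cat("<calens_fit> ", nrow(x$history), " epochs, best epoch ",
      x$best_epoch, " (val loss ",
      format(min(x$history$val_loss), digits = 5), ")\n", sep = "")
  invisible(x)
}

#' Evaluate a trained classifier
#'
#' @param fit a `calens_fit` or `calens_net` classifier.
#' @param x test input array.
#' @param labels 0-based true classes.
#' @return a [metric_report()].
#' @export
evaluate <- function(fit, x, labels) {
  net <- if (inherits(fit, "calens_fit")) fit$net else fit
  if (length(labels) < 1L || dim(x)[1] != length(labels)) {
    stop("test set must be non-empty and match the labels", call. = FALSE)
  }
  metric_report(labels, predict(net, x))
}

#' Evaluate a trained segmenter
#'
#' Thresholds predicted foreground probabilities at 0.5 and averages
#' Dice, IoU and pixel accuracy over the test pairs.
#'
#' @param fit a `calens_fit` or `calens_net` segmenter.
#' @param x test image array.
#' @param masks `N x H x W` ground-truth masks.
#' @return named numeric `c(dice, iou, accuracy)`.
#' @export
evaluate_segmentation <- function(fit, x, masks) {
  net <- if (inherits(fit, "calens_fit")) fit$net else fit
  p <- predict(net, x)
  N <- dim(x)[1]
  out <- c(dice = 0, iou = 0, accuracy = 0)
  for (i in seq_len(N)) {
    pm <- (matrix(p[i, , ], dim(p)[2], dim(p)[3]) >= 0.5) * 1
    gm <- matrix(masks[i, , ], dim(masks)[2], dim(masks)[3])
    out <- out + dice_iou_pixelacc(gm, pm) / N
  }
  out
}

#' Train a model-level feature-fusion ensemble
#'
#' Extracts each constituent classifier's deepest-convolutional-layer
#' (`"dcl"`) feature maps, concatenates them along channels, and trains a
#' [fuse_features()] head on top. The constituents are used as frozen
#' feature extractors.
#'
#' @param classifiers list of trained `calens_net` classifiers (>= 2).
#' @param x training input array.
#' @param labels 0-based training labels.
#' @param cfg a [train_config()] for the head.
#' @param fused_channels 1x1-convolution width (`NULL`: one constituent's
#'   width).
#' @param seed head initialization seed.
#' @return list of class `model_ensemble`: `head` (`calens_fit`),
#'   `classifiers`.
#' @export
model_level_ensemble <- function(classifiers, x, labels, cfg,
                                 fused_channels = NULL, seed = 1) {
  if (length(classifiers) < 2L) stop("need at least two classifiers", call. = FALSE)
  stacks <- lapply(classifiers, extract_features, x = x)
  head <- fuse_features(stacks, fused_channels = fused_channels, seed = seed)
  fit <- train(head, concat_features(stacks), labels, cfg)
  structure(list(head = fit, classifiers = classifiers),
            class = "model_ensemble")
}

#' Predict from a model-level ensemble
#'
#' @param object a `model_ensemble`.
#' @param x input array.
#' @param ... unused.
#' @return `N x K` probability matrix.
#' @export
predict.model_ensemble <- function(object, x, ...) {
  stacks <- lapply(object$classifiers, extract_features, x = x)
  predict(object$head$net, concat_features(stacks))
}
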