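# A small, dependency-free layer engine for the desk-scale networks used
# throughout the package: the tiny encoder-decoder segmenter, the
# classifier head and the feature-fusion head. Inputs are N x H x W x C
# arrays; convolutions are stride-1 with explicit zero padding and are
# computed by gathering patches into a matrix (im2col) so that both the
# forward and the backward pass are single matrix products. Parameters
# live in an environment so that truncated views of a network genuinely
# share (and co-mutate) weights with their parent.

# --- im2col index map -------------------------------------------------------

# Flat indices into a zero-padded (Hp x Wp x C) volume for every output
# position (rows) and every patch element (columns), for a k x k stride-1
# convolution with padding `pad`. Output size is (H + 2 pad - k + 1) square
# in each dimension. Memoized per shape: the same maps are reused for
# every batch of a training run.
.conv_index_cache <- new.env(parent = emptyenv())

.conv_index <- function(H, W, C, k, pad) {
  key <- paste(H, W, C, k, pad, sep = "_")
  hit <- .conv_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- .conv_index_build(H, W, C, k, pad)
  .conv_index_cache[[key]] <- out
  out
}

.conv_index_build <- function(H, W, C, k, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- Hp - k + 1L; Wo <- Wp - k + 1L
  oh <- rep(seq_len(Ho), times = Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  idx <- matrix(0L, Ho * Wo, k * k * C)
  q <- 0L
  for (c in seq_len(C)) {
    for (kw in seq_len(k)) {
      for (kh in seq_len(k)) {
        q <- q + 1L
        idx[, q] <- (oh + kh - 1L) + (ow + kw - 2L) * Hp + (c - 1L) * Hp * Wp
      }
    }
  }
  list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
}

.pad_batch <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  out[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out
}

.conv_forward <- function(x, Wm, b, k, pad, act) {
  d <- dim(x)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  ci <- .conv_index(H, W, C, k, pad)
  P <- matrix(.pad_batch(x, pad), N)
  Am <- matrix(array(P[, as.vector(ci$idx), drop = FALSE],
                     c(N, ci$Ho * ci$Wo, ncol(ci$idx))),
               N * ci$Ho * ci$Wo, ncol(ci$idx))
  Y <- sweep(Am %*% Wm, 2L, b, "+")
  pre <- array(Y, c(N, ci$Ho, ci$Wo, ncol(Wm)))
  out <- switch(act,
    relu = pmax(pre, 0),
    lrelu = ifelse(pre > 0, pre, 0.1 * pre),
    pre
  )
  dim(out) <- dim(pre)
  list(out = out, cache = list(Am = Am, ci = ci, dims = d, pre = pre, act = act))
}

.conv_backward <- function(dout, Wm, cache) {
  d <- cache$dims; ci <- cache$ci
  N <- d[1]
  if (cache$act == "relu") {
    dout <- dout * (cache$pre > 0)
  } else if (cache$act == "lrelu") {
    dout <- dout * ifelse(cache$pre > 0, 1, 0.1)
  }
  dYm <- matrix(dout, N * ci$Ho * ci$Wo, ncol(Wm))
  dW <- crossprod(cache$Am, dYm)
  db <- colSums(dYm)
  dAm <- tcrossprod(dYm, Wm)
  dA3 <- array(dAm, c(N, ci$Ho * ci$Wo, ncol(cache$Am)))
  dP <- matrix(0, N, ci$Hp * ci$Wp * d[4])
  for (q in seq_len(dim(dA3)[3])) {
    cols <- ci$idx[, q]
    dP[, cols] <- dP[, cols] + dA3[, , q]
  }
  pad <- (ci$Hp - d[2]) %/% 2L
  dXp <- array(dP, c(N, ci$Hp, ci$Wp, d[4]))
  dX <- dXp[, pad + seq_len(d[2]), pad + seq_len(d[3]), , drop = FALSE]
  list(dx = dX, dW = dW, db = db)
}

.maxpool_forward <- function(x) {
  d <- dim(x)
  odd_r <- seq(1L, d[2], 2L); evn_r <- seq(2L, d[2], 2L)
  odd_c <- seq(1L, d[3], 2L); evn_c <- seq(2L, d[3], 2L)
  x11 <- x[, odd_r, odd_c, , drop = FALSE]
  x21 <- x[, evn_r, odd_c, , drop = FALSE]
  x12 <- x[, odd_r, evn_c, , drop = FALSE]
  x22 <- x[, evn_r, evn_c, , drop = FALSE]
  m <- pmax(x11, x21, x12, x22)
  dim(m) <- dim(x11)
  list(out = m, cache = list(x11 = x11, x21 = x21, x12 = x12, x22 = x22,
                             m = m, dims = d))
}

.maxpool_backward <- function(dout, cache) {
  d <- cache$dims
  w11 <- cache$x11 == cache$m
  w21 <- (cache$x21 == cache$m) & !w11
  w12 <- (cache$x12 == cache$m) & !w11 & !w21
  w22 <- !(w11 | w21 | w12)
  dx <- array(0, d)
  odd_r <- seq(1L, d[2], 2L); evn_r <- seq(2L, d[2], 2L)
  odd_c <- seq(1L, d[3], 2L); evn_c <- seq(2L, d[3], 2L)
  dx[, odd_r, odd_c, ] <- dout * w11
  dx[, evn_r, odd_c, ] <- dout * w21
  dx[, odd_r, evn_c, ] <- dout * w12
  dx[, evn_r, evn_c, ] <- dout * w22
  dx
}

.upsample_forward <- function(x) {
  d <- dim(x)
  out <- x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), ,
           drop = FALSE]
  list(out = out, cache = list(dims = d))
}

.upsample_backward <- function(dout, cache) {
  d <- cache$dims
  odd_r <- seq(1L, 2L * d[2], 2L); evn_r <- seq(2L, 2L * d[2], 2L)
  odd_c <- seq(1L, 2L * d[3], 2L); evn_c <- seq(2L, 2L * d[3], 2L)
  dout[, odd_r, odd_c, , drop = FALSE] + dout[, evn_r, odd_c, , drop = FALSE] +
    dout[, odd_r, evn_c, , drop = FALSE] + dout[, evn_r, evn_c, , drop = FALSE]
}

.gap_forward <- function(x) {
  d <- dim(x)
  M1 <- matrix(x, d[1] * d[2] * d[3], d[4])
  grp <- rep_len(seq_len(d[1]), nrow(M1))
  out <- rowsum(M1, grp) / (d[2] * d[3])
  rownames(out) <- NULL
  list(out = out, cache = list(dims = d, grp = grp))
}

.gap_backward <- function(dout, cache) {
  d <- cache$dims
  array(dout[cache$grp, , drop = FALSE] / (d[2] * d[3]), d)
}

# --- network object ---------------------------------------------------------

# A layer descriptor is list(op, name, ...). Supported ops:
#   conv(k, filters, pad, act)   zeropad(p)   pool2   up2
#   concat(with = <tap name>)    gap          dense(units)
# Any layer may carry `tap = "<name>"` to expose its output for later
# concat layers and for encoder truncation.

.infer_shapes <- function(layers, input_shape) {
  shape <- input_shape  # c(H, W, C) or c(D) after gap
  taps <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    shape <- switch(ly$op,
      conv = {
        stopifnot(length(shape) == 3L)
        c(shape[1] + 2L * ly$pad - ly$k + 1L,
          shape[2] + 2L * ly$pad - ly$k + 1L, ly$filters)
      },
      zeropad = c(shape[1] + 2L * ly$p, shape[2] + 2L * ly$p, shape[3]),
      pool2 = {
        if (shape[1] %% 2L || shape[2] %% 2L) {
          stop("pool2 needs even spatial dims, got ", shape[1], "x", shape[2],
               call. = FALSE)
        }
        c(shape[1] %/% 2L, shape[2] %/% 2L, shape[3])
      },
      up2 = c(shape[1] * 2L, shape[2] * 2L, shape[3]),
      concat = {
        tshape <- taps[[ly$with]]
        if (is.null(tshape)) stop("unknown tap '", ly$with, "'", call. = FALSE)
        if (!identical(tshape[1:2], shape[1:2])) {
          stop("concat spatial shapes differ", call. = FALSE)
        }
        c(shape[1], shape[2], shape[3] + tshape[3])
      },
      gap = shape[3],
      dense = ly$units,
      stop("unknown op ", ly$op, call. = FALSE)
    )
    layers[[i]]$in_shape <- NULL
    layers[[i]]$out_shape <- shape
    if (!is.null(ly$tap)) taps[[ly$tap]] <- shape
  }
  layers
}

.init_layer_params <- function(layers, input_shape, params, seed) {
  with_seed(seed, {
    shape <- input_shape
    for (ly in layers) {
      if (ly$op == "conv" && is.null(params[[ly$name]])) {
        fan_in <- ly$k * ly$k * shape[3]
        params[[ly$name]] <- list(
          W = matrix(stats::rnorm(fan_in * ly$filters, sd = sqrt(2 / fan_in)),
                     fan_in, ly$filters),
          b = rep(0, ly$filters)
        )
      } else if (ly$op == "dense" && is.null(params[[ly$name]])) {
        fan_in <- prod(shape)
        # "small" init for output heads starts training near the uniform
        # (maximum-entropy) prediction without blocking gradient flow
        sd0 <- if (identical(ly$init, "small")) 0.01 else sqrt(2 / fan_in)
        params[[ly$name]] <- list(
          W = matrix(stats::rnorm(fan_in * ly$units, sd = sd0), fan_in, ly$units),
          b = rep(0, ly$units)
        )
      }
      shape <- ly$out_shape
    }
  })
  invisible(params)
}

new_network <- function(layers, input_shape, kind, seed = 1, params = NULL) {
  layers <- .infer_shapes(layers, input_shape)
  params <- params %||% new.env(parent = emptyenv())
  .init_layer_params(layers, input_shape, params, seed)
  structure(list(layers = layers, input_shape = input_shape, kind = kind,
                 params = params),
            class = "calens_net")
}

#' @export
print.calens_net <- function(x, ...) {
  cat("<calens_net> kind=", x$kind, ", input ",
      paste(x$input_shape, collapse = "x"), "\n", sep = "")
  for (ly in x$layers) {
    cat(sprintf("  %-8s %-12s -> %s%s\n", ly$op, ly$name %||% "",
                paste(ly$out_shape, collapse = "x"),
                if (!is.null(ly$tap)) paste0("  [tap ", ly$tap, "]") else ""))
  }
  cat("  parameters: ", network_n_params(x), "\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net a `calens_net`.
#' @return integer count.
#' @export
network_n_params <- function(net) {
  sum(vapply(ls(net$params), function(nm) {
    p <- net$params[[nm]]
    length(p$W) + length(p$b)
  }, numeric(1)))
}

#' Deep-copy a network (parameters included)
#'
#' Networks share parameters through an environment; use this to obtain an
#' independent copy whose weights no longer co-mutate with the original.
#'
#' @param net a `calens_net`.
#' @return an independent `calens_net`.
#' @export
clone_network <- function(net) {
  params <- new.env(parent = emptyenv())
  for (nm in ls(net$params)) params[[nm]] <- net$params[[nm]]
  structure(list(layers = net$layers, input_shape = net$input_shape,
                 kind = net$kind, params = params),
            class = "calens_net")
}

.net_forward <- function(net, x, want_cache = FALSE, tap_stop = NULL) {
  caches <- if (want_cache) vector("list", length(net$layers)) else NULL
  taps <- list()
  out <- x
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    res <- switch(ly$op,
      conv = {
        p <- net$params[[ly$name]]
        .conv_forward(out, p$W, p$b, ly$k, ly$pad, ly$act)
      },
      zeropad = list(out = .pad_batch(out, ly$p), cache = list(p = ly$p)),
      pool2 = .maxpool_forward(out),
      up2 = .upsample_forward(out),
      concat = {
        tp <- taps[[ly$with]]
        d <- dim(out)
        merged <- array(0, c(d[1], d[2], d[3], d[4] + dim(tp)[4]))
        merged[, , , seq_len(d[4])] <- out
        merged[, , , d[4] + seq_len(dim(tp)[4])] <- tp
        list(out = merged, cache = list(c_main = d[4], c_tap = dim(tp)[4]))
      },
      gap = .gap_forward(out),
      dense = {
        p <- net$params[[ly$name]]
        xf <- if (is.matrix(out)) out else matrix(out, dim(out)[1])
        list(out = sweep(xf %*% p$W, 2L, p$b, "+"),
             cache = list(xf = xf, in_dim = dim(out)))
      }
    )
    out <- res$out
    if (want_cache) caches[[i]] <- res$cache
    if (!is.null(ly$tap)) {
      taps[[ly$tap]] <- out
      if (!is.null(tap_stop) && identical(ly$tap, tap_stop)) {
        return(list(out = out, caches = caches, taps = taps, stopped_at = i))
      }
    }
  }
  list(out = out, caches = caches, taps = taps)
}

# Backward pass: `dout` is the gradient at the network output. Returns a
# list of parameter gradients keyed by layer name.
.net_backward <- function(net, fw, dout) {
  grads <- list()
  tap_grads <- list()
  g <- dout
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (!is.null(ly$tap) && !is.null(tap_grads[[ly$tap]])) {
      g <- g + tap_grads[[ly$tap]]
    }
    cache <- fw$caches[[i]]
    g <- switch(ly$op,
      conv = {
        p <- net$params[[ly$name]]
        bk <- .conv_backward(g, p$W, cache)
        grads[[ly$name]] <- list(W = bk$dW, b = bk$db)
        bk$dx
      },
      zeropad = {
        d <- dim(g); p <- cache$p
        g[, p + seq_len(d[2] - 2L * p), p + seq_len(d[3] - 2L * p), ,
          drop = FALSE]
      },
      pool2 = .maxpool_backward(g, cache),
      up2 = .upsample_backward(g, cache),
      concat = {
        cm <- cache$c_main; ct <- cache$c_tap
        tap_layer <- net$layers[[i]]$with
        gt <- g[, , , cm + seq_len(ct), drop = FALSE]
        tap_grads[[tap_layer]] <- if (is.null(tap_grads[[tap_layer]])) gt
                                  else tap_grads[[tap_layer]] + gt
        g[, , , seq_len(cm), drop = FALSE]
      },
      gap = .gap_backward(g, cache),
      dense = {
        grads[[ly$name]] <- list(W = crossprod(cache$xf, g), b = colSums(g))
        dx <- tcrossprod(g, net$params[[ly$name]]$W)
        if (length(cache$in_dim) > 2L) dim(dx) <- cache$in_dim
        dx
      }
    )
  }
  grads
}

# --- optimizers -------------------------------------------------------------

.opt_init <- function(net) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  for (nm in ls(net$params)) {
    p <- net$params[[nm]]
    st[[nm]] <- list(vW = p$W * 0, vb = p$b * 0, mW = p$W * 0, mb = p$b * 0)
  }
  st
}

.opt_step <- function(net, grads, st, optimizer, lr, momentum = 0.9,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    p <- net$params[[nm]]
    g <- grads[[nm]]
    s <- st[[nm]]
    if (optimizer == "sgd") {
      s$vW <- momentum * s$vW - lr * g$W
      s$vb <- momentum * s$vb - lr * g$b
      p$W <- p$W + s$vW
      p$b <- p$b + s$vb
    } else {
      s$mW <- beta1 * s$mW + (1 - beta1) * g$W
      s$mb <- beta1 * s$mb + (1 - beta1) * g$b
      s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
      s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
      corr1 <- 1 - beta1^st$t
      corr2 <- 1 - beta2^st$t
      p$W <- p$W - lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
      p$b <- p$b - lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    }
    st[[nm]] <- s
    net$params[[nm]] <- p
  }
  invisible(NULL)
}

.snapshot_params <- function(net) {
  out <- list()
  for (nm in ls(net$params)) out[[nm]] <- net$params[[nm]]
  out
}

.restore_params <- function(net, snap) {
  for (nm in names(snap)) net$params[[nm]] <- snap[[nm]]
  invisible(NULL)
}

#' Network predictions
#'
#' Runs the forward pass in mini-batches and applies the output
#' nonlinearity implied by the network kind: row softmax for classifier
#' and fusion heads, element-wise sigmoid for segmenters.
#'
#' @param object a `calens_net`.
#' @param x input array `N x H x W x C`.
#' @param batch_size forward mini-batch size.
#' @param ... unused.
#' @return `N x K` probability matrix, or an `N x H x W` array of
#'   foreground probabilities for segmenters.
#' @export
predict.calens_net <- function(object, x, batch_size = 64L, ...) {
  N <- dim(x)[1]
  outs <- vector("list", ceiling(N / batch_size))
  for (bi in seq_along(outs)) {
    rows <- ((bi - 1L) * batch_size + 1L):min(bi * batch_size, N)
    z <- .net_forward(object, x[rows, , , , drop = FALSE])$out
    outs[[bi]] <- z
  }
  if (object$kind == "segmenter") {
    z <- array(0, c(N, dim(outs[[1]])[2], dim(outs[[1]])[3]))
    at <- 1L
    for (o in outs) {
      n <- dim(o)[1]
      z[at:(at + n - 1L), , ] <- sigmoid(array(o[, , , 1L, drop = FALSE],
                                               dim(o)[1:3]))
      at <- at + n
    }
    z
  } else {
    softmax(do.call(rbind, outs))
  }
}
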