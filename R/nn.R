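# Compact CPU training engine for the baseline classifiers: explicit
# forward/backward layers (dense, 2D/3D convolution, PReLU, batch norm, max
# pooling, residual blocks, point-cloud shared encoders) with an Adam
# optimizer, cross-entropy loss and Kaiming-normal initialization. Batch
# inputs are matrices with ONE SAMPLE PER COLUMN (so each sample is one
# contiguous memory block); per-sample feature layout is channel-major with
# spatial dimensions fastest-last.

.kaiming <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))

.new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e$params <- character(0)
  e
}

.layer_dense <- function(n_in, n_out) {
  l <- .new_layer("dense", n_in = n_in, n_out = n_out)
  l$W <- matrix(.kaiming(n_in, n_in * n_out), n_in, n_out)
  l$b <- numeric(n_out)
  l$params <- c("W", "b")
  l$out_shape <- n_out
  l
}

.layer_conv3d <- function(dims, K, k, stride = 1L, pad = 0L) {
  C <- dims[1]
  l <- .new_layer("conv3d", dims = as.integer(dims), K = K, k = k,
                  stride = as.integer(stride), pad = as.integer(pad))
  fan_in <- C * k^3
  l$W <- matrix(.kaiming(fan_in, K * fan_in), K, fan_in)
  l$b <- numeric(K)
  l$params <- c("W", "b")
  osp <- (dims[-1] - k + 2 * pad) %/% stride + 1L
  if (any(osp < 1)) stop("convolution output size would be empty")
  l$out_shape <- c(K, osp)
  l
}

.layer_conv2d <- function(dims, K, k, stride = 1L, pad = 0L) {
  C <- dims[1]
  l <- .new_layer("conv2d", dims = as.integer(dims), K = K, k = k,
                  stride = as.integer(stride), pad = as.integer(pad))
  fan_in <- C * k^2
  l$W <- matrix(.kaiming(fan_in, K * fan_in), K, fan_in)
  l$b <- numeric(K)
  l$params <- c("W", "b")
  osp <- (dims[-1] - k + 2 * pad) %/% stride + 1L
  if (any(osp < 1)) stop("convolution output size would be empty")
  l$out_shape <- c(K, osp)
  l
}

.layer_prelu <- function(shape, a = 0.25) {
  l <- .new_layer("prelu", out_shape = shape)
  l$a <- a
  l$params <- "a"
  l
}

.layer_relu <- function(shape) .new_layer("relu", out_shape = shape)

.layer_maxpool <- function(dims, k, stride = k, pad = 0L) {
  osp <- (dims[-1] - k + 2 * pad) %/% stride + 1L
  .new_layer("maxpool", dims = as.integer(dims), k = as.integer(k),
             stride = as.integer(stride), pad = as.integer(pad),
             out_shape = c(dims[1], osp))
}

.layer_batchnorm <- function(dims, momentum = 0.1, eps = 1e-5) {
  C <- dims[1]
  l <- .new_layer("batchnorm", dims = as.integer(dims), momentum = momentum,
                  eps = eps, out_shape = dims)
  l$gamma <- rep(1, C)
  l$beta <- rep(0, C)
  l$run_mean <- rep(0, C)
  l$run_var <- rep(1, C)
  l$params <- c("gamma", "beta")
  l
}

.layer_gap <- function(dims)                 # global average pool -> C
  .new_layer("gap", dims = as.integer(dims), out_shape = dims[1])

.layer_reshape_points <- function(n_points)  # n x (K*3) -> (n*K) x 3
  .new_layer("reshape_points", n_points = as.integer(n_points), out_shape = 3L)

.layer_pool_points <- function(n_points, n_feat)  # (n*K) x F -> n x F (max)
  .new_layer("pool_points", n_points = as.integer(n_points),
             out_shape = n_feat)

.layer_resblock <- function(dims, K, stride = 1L) {
  C <- dims[1]
  l <- .new_layer("resblock", dims = as.integer(dims))
  l$conv1 <- .layer_conv2d(dims, K, 3L, stride, 1L)
  l$bn1 <- .layer_batchnorm(l$conv1$out_shape)
  l$conv2 <- .layer_conv2d(l$conv1$out_shape, K, 3L, 1L, 1L)
  l$bn2 <- .layer_batchnorm(l$conv2$out_shape)
  l$downsample <- if (stride != 1L || C != K) {
    ds <- .layer_conv2d(dims, K, 1L, stride, 0L)
    list(conv = ds, bn = .layer_batchnorm(ds$out_shape))
  } else NULL
  l$out_shape <- l$conv2$out_shape
  l
}

# per-channel helpers: X is (C*S) x n, channel-major rows
.channel_stat <- function(X, C, S, fun) {
  vapply(seq_len(C),
         function(c) fun(X[((c - 1) * S + 1):(c * S), , drop = FALSE]), 0)
}

.forward_layer <- function(l, X, training) {
  switch(l$type,
    dense = {
      l$X <- X
      crossprod(l$W, X) + l$b
    },
    conv3d = {
      l$X <- X
      .conv3d_fw_cpp(X, l$dims, l$W, l$b, l$k, l$stride, l$pad)
    },
    conv2d = {
      l$X <- X
      .conv2d_fw_cpp(X, l$dims, l$W, l$b, l$k, l$stride, l$pad)
    },
    prelu = {
      l$X <- X
      pos <- X > 0
      X * pos + (l$a * X) * !pos
    },
    relu = {
      l$mask <- X > 0
      X * l$mask
    },
    maxpool = {
      r <- .maxpool_fw_cpp(X, l$dims, l$k, l$stride, l$pad)
      l$argmax <- r$argmax
      l$in_size <- nrow(X)
      r$Y
    },
    batchnorm = {
      C <- l$dims[1]; S <- prod(l$dims[-1])
      if (training) {
        mu <- .channel_stat(X, C, S, mean)
        va <- .channel_stat(X, C, S, function(m) mean((m - mean(m))^2))
        l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
        l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * va
      } else {
        mu <- l$run_mean; va <- l$run_var
      }
      mu_e <- rep(mu, each = S); sd_e <- rep(sqrt(va + l$eps), each = S)
      xhat <- (X - mu_e) / sd_e            # recycles down columns
      l$xhat <- xhat; l$sd_e <- sd_e
      xhat * rep(l$gamma, each = S) + rep(l$beta, each = S)
    },
    gap = {
      C <- l$dims[1]; S <- prod(l$dims[-1])
      l$S <- S
      out <- matrix(0, C, ncol(X))
      for (c in seq_len(C))
        out[c, ] <- colMeans(X[((c - 1) * S + 1):(c * S), , drop = FALSE])
      out
    },
    reshape_points = {
      K <- l$n_points
      l$n <- ncol(X)
      # column s = (p1x p1y p1z p2x ...) -> 3 x (K*n), points as columns
      dim(X) <- c(3L, K * ncol(X))
      X
    },
    pool_points = {
      K <- l$n_points
      n <- ncol(X) %/% K
      f <- nrow(X)
      l$n <- n
      out <- matrix(0, f, n)
      arg <- matrix(0L, f, n)
      for (s in seq_len(n)) {
        cols <- ((s - 1) * K + 1):(s * K)
        block <- X[, cols, drop = FALSE]      # f x K
        w <- max.col(block, ties.method = "first")
        arg[, s] <- cols[w]
        out[, s] <- block[cbind(seq_len(f), w)]
      }
      l$argcol <- arg
      l$in_cols <- ncol(X)
      out
    },
    resblock = {
      l$Xin <- X
      h <- .forward_layer(l$conv1, X, training)
      h <- .forward_layer(l$bn1, h, training)
      l$mask1 <- h > 0
      h <- h * l$mask1
      h <- .forward_layer(l$conv2, h, training)
      h <- .forward_layer(l$bn2, h, training)
      idt <- if (is.null(l$downsample)) X else {
        z <- .forward_layer(l$downsample$conv, X, training)
        .forward_layer(l$downsample$bn, z, training)
      }
      s <- h + idt
      l$mask_out <- s > 0
      s * l$mask_out
    },
    stop("unknown layer type: ", l$type))
}

.backward_layer <- function(l, dY, need_dx = TRUE) {
  switch(l$type,
    dense = {
      l$dW <- tcrossprod(l$X, dY)
      l$db <- rowSums(dY)
      if (need_dx) l$W %*% dY else NULL
    },
    conv3d = {
      r <- .conv3d_bw_cpp(l$X, dY, l$dims, l$W, l$k, l$stride, l$pad, need_dx)
      l$dW <- r$dW; l$db <- as.numeric(r$db)
      if (need_dx) r$dX else NULL
    },
    conv2d = {
      r <- .conv2d_bw_cpp(l$X, dY, l$dims, l$W, l$k, l$stride, l$pad, need_dx)
      l$dW <- r$dW; l$db <- as.numeric(r$db)
      if (need_dx) r$dX else NULL
    },
    prelu = {
      neg <- l$X <= 0
      l$da <- sum(dY[neg] * l$X[neg])
      dY * ifelse(neg, l$a, 1)
    },
    relu = dY * l$mask,
    maxpool = .maxpool_bw_cpp(dY, l$argmax, l$in_size),
    batchnorm = {
      C <- l$dims[1]; S <- prod(l$dims[-1])
      l$dgamma <- .channel_stat(dY * l$xhat, C, S, sum)
      l$dbeta <- .channel_stat(dY, C, S, sum)
      dxhat <- dY * rep(l$gamma, each = S)
      dx <- dxhat
      for (c in seq_len(C)) {
        rows <- ((c - 1) * S + 1):(c * S)
        dxh <- dxhat[rows, , drop = FALSE]
        xh <- l$xhat[rows, , drop = FALSE]
        sd <- l$sd_e[(c - 1) * S + 1]
        dx[rows, ] <- (dxh - mean(dxh) - xh * mean(dxh * xh)) / sd
      }
      dx
    },
    gap = {
      C <- l$dims[1]; S <- l$S
      dY[rep(seq_len(C), each = S), , drop = FALSE] / S
    },
    reshape_points = {
      dim(dY) <- c(nrow(dY) * l$n_points, l$n)
      dY
    },
    pool_points = {
      f <- nrow(dY)
      dX <- matrix(0, f, l$in_cols)
      for (s in seq_len(ncol(dY)))
        dX[cbind(seq_len(f), l$argcol[, s])] <-
          dX[cbind(seq_len(f), l$argcol[, s])] + dY[, s]
      dX
    },
    resblock = {
      dS <- dY * l$mask_out
      dh <- .backward_layer(l$bn2, dS)
      dh <- .backward_layer(l$conv2, dh)
      dh <- dh * l$mask1
      dh <- .backward_layer(l$bn1, dh)
      dx1 <- .backward_layer(l$conv1, dh, need_dx)
      dx2 <- if (is.null(l$downsample)) dS else {
        z <- .backward_layer(l$downsample$bn, dS)
        .backward_layer(l$downsample$conv, z, need_dx)
      }
      if (need_dx) dx1 + dx2 else NULL
    },
    stop("unknown layer type: ", l$type))
}

.collect_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    out <- c(out, list(l))
    if (l$type == "resblock") {
      out <- c(out, list(l$conv1, l$bn1, l$conv2, l$bn2))
      if (!is.null(l$downsample))
        out <- c(out, list(l$downsample$conv, l$downsample$bn))
    }
  }
  out
}

#' Build a baseline classifier
#'
#' Three architectures matching the four feature representations:
#' `"pointnet_like"` (shared per-point encoder, symmetric max pooling,
#' dense head; permutation invariant) for coordinate/surface point clouds,
#' `"voxnet_prelu"` (two 3D convolutions with parametric rectifiers, max
#' pooling, dense head) for 32^3 voxel grids, and `"resnet18_1ch"`
#' (ResNet-18 with a single input channel) for 128x128 Hilbert images.
#'
#' @param arch One of `"pointnet_like"`, `"voxnet_prelu"`, `"resnet18_1ch"`.
#' @param n_classes Output class count (20 or 400 for the fragment tasks).
#' @param input_shape Point count for the point model (default 24), grid side
#'   for the voxel model (32), image side for the image model (128).
#' @param width Channel multiplier (1 = the cited reference sizes; smaller
#'   values give the scaled-down models used for CPU-sized experiments).
#' @param seed Initialization seed (Kaiming normal for convolutions).
#' @return A `flexfrag_model`.
#' @export
build_model <- function(arch = c("pointnet_like", "voxnet_prelu",
                                 "resnet18_1ch"),
                        n_classes, input_shape = NULL, width = 1,
                        seed = 1L) {
  arch <- match.arg(arch)
  stopifnot(n_classes >= 2)
  w <- function(x) max(4L, as.integer(round(x * width)))
  .with_seed(seed, {
    layers <- switch(arch,
      pointnet_like = {
        K <- input_shape %||% 24L
        f1 <- w(64); f2 <- w(128); f3 <- w(256); fh <- w(128)
        list(.layer_reshape_points(K),
             .layer_dense(3L, f1), .layer_relu(f1),
             .layer_dense(f1, f2), .layer_relu(f2),
             .layer_dense(f2, f3), .layer_relu(f3),
             .layer_pool_points(K, f3),
             .layer_dense(f3, fh), .layer_relu(fh),
             .layer_dense(fh, n_classes))
      },
      voxnet_prelu = {
        side <- input_shape %||% 32L
        f1 <- w(32); f2 <- w(32); fh <- w(128)
        c1 <- .layer_conv3d(c(1L, side, side, side), f1, 5L, 2L)
        p1 <- .layer_prelu(c1$out_shape)
        c2 <- .layer_conv3d(c1$out_shape, f2, 3L, 1L)
        p2 <- .layer_prelu(c2$out_shape)
        mp <- .layer_maxpool(c2$out_shape, 2L)
        nf <- prod(mp$out_shape)
        d1 <- .layer_dense(nf, fh)
        p3 <- .layer_prelu(fh)
        d2 <- .layer_dense(fh, n_classes)
        list(c1, p1, c2, p2, mp, d1, p3, d2)
      },
      resnet18_1ch = {
        side <- input_shape %||% 128L
        f <- c(w(64), w(128), w(256), w(512))
        c1 <- .layer_conv2d(c(1L, side, side), f[1], 7L, 2L, 3L)
        bn1 <- .layer_batchnorm(c1$out_shape)
        r1 <- .layer_relu(c1$out_shape)
        mp <- .layer_maxpool(c1$out_shape, 3L, 2L, 1L)
        blocks <- list()
        shape <- mp$out_shape
        for (stage in 1:4) {
          stride <- if (stage == 1) 1L else 2L
          b1 <- .layer_resblock(shape, f[stage], stride)
          b2 <- .layer_resblock(b1$out_shape, f[stage], 1L)
          shape <- b2$out_shape
          blocks <- c(blocks, list(b1, b2))
        }
        gp <- .layer_gap(shape)
        fc <- .layer_dense(shape[1], n_classes)
        c(list(c1, bn1, r1, mp), blocks, list(gp, fc))
      })
    input_size <- switch(arch,
      pointnet_like = 3L * (input_shape %||% 24L),
      voxnet_prelu = as.integer((input_shape %||% 32L)^3),
      resnet18_1ch = as.integer((input_shape %||% 128L)^2))
    structure(list(arch = arch, n_classes = as.integer(n_classes),
                   layers = layers, width = width, input_size = input_size),
              class = "flexfrag_model")
  })
}

#' @export
print.flexfrag_model <- function(x, ...) {
  np <- sum(vapply(.collect_layers(x$layers), function(l)
    sum(vapply(l$params, function(p) length(get(p, envir = l)), 0)), 0))
  cat(sprintf("<flexfrag_model %s: %d classes, %s parameters>\n", x$arch,
              x$n_classes, format(np, big.mark = ",")))
  invisible(x)
}

#' Forward pass: class scores for a batch
#' @param model A `flexfrag_model`.
#' @param X Matrix features x n, one sample per column (flattened
#'   channel-major input).
#' @param training Use batch statistics and cache activations.
#' @return Matrix n_classes x n of scores (logits), one column per sample.
#' @export
model_forward <- function(model, X, training = FALSE) {
  if (!is.null(model$input_size) && nrow(X) != model$input_size)
    stop(sprintf("input feature shape mismatch: got %d values per sample, the %s model expects %d",
                 nrow(X), model$arch, model$input_size), call. = FALSE)
  for (l in model$layers) X <- .forward_layer(l, X, training)
  X
}

.model_backward <- function(model, dY) {
  layers <- model$layers
  for (i in rev(seq_along(layers)))
    dY <- .backward_layer(layers[[i]], dY, need_dx = i > 1)
  invisible(NULL)
}

.softmax_ce <- function(logits, y) {
  # logits: C x n; y: integer 1..C; returns loss and gradient wrt logits
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), `/`)
  n <- ncol(logits)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(n))], 1e-12)))
  g <- p
  g[cbind(y, seq_len(n))] <- g[cbind(y, seq_len(n))] - 1
  list(loss = loss, grad = g / n)
}

.adam_step <- function(model, lr, beta1, beta2, eps, t) {
  for (l in .collect_layers(model$layers)) {
    for (p in l$params) {
      g <- get(paste0("d", p), envir = l)
      th <- get(p, envir = l)
      mkey <- paste0(".m_", p); vkey <- paste0(".v_", p)
      m <- if (exists(mkey, envir = l)) get(mkey, envir = l) else 0 * g
      v <- if (exists(vkey, envir = l)) get(vkey, envir = l) else 0 * g
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      assign(p, th - lr * mh / (sqrt(vh) + eps), envir = l)
      assign(mkey, m, envir = l)
      assign(vkey, v, envir = l)
    }
  }
}

#' Fixed training protocol configuration
#'
#' Defaults follow the benchmark protocol: Adam with momenta (0.9, 0.999),
#' initial learning rate 1e-3 rescaled by 0.5 every 30 epochs, 120 epochs,
#' mini-batch 64, cross-entropy loss, Kaiming-normal convolution
#' initialization, and early termination once test accuracy exceeds 99.5%.
#' (A 1e-4 initial rate is the documented exception preset for several
#' community models outside the baseline set.)
#'
#' @param initial_lr Initial learning rate.
#' @param lr_factor Multiplicative decay factor.
#' @param lr_step_epochs Epoch interval between decays.
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size.
#' @param beta1,beta2 Adam momentum factors.
#' @param early_stop_acc Test-accuracy (%) termination threshold.
#' @param seed RNG seed (shuffling, initialization of the run).
#' @return A `train_config` list.
#' @export
train_config <- function(initial_lr = 1e-3, lr_factor = 0.5,
                         lr_step_epochs = 30L, epochs = 120L,
                         batch_size = 64L, beta1 = 0.9, beta2 = 0.999,
                         early_stop_acc = 99.5, seed = 1L) {
  stopifnot(initial_lr > 0, lr_factor > 0, lr_step_epochs > 0, epochs > 0,
            batch_size > 0, early_stop_acc > 0, early_stop_acc <= 100)
  structure(list(initial_lr = initial_lr, lr_factor = lr_factor,
                 lr_step_epochs = as.integer(lr_step_epochs),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, early_stop_acc = early_stop_acc,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch under the step schedule
#' @param config A `train_config`.
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @return `initial_lr * lr_factor^floor(epoch / lr_step_epochs)`.
#' @export
lr_at_epoch <- function(config, epoch) {
  if (any(epoch < 0)) stop("epoch must be nonnegative")
  config$initial_lr * config$lr_factor^(epoch %/% config$lr_step_epochs)
}

#' Train a classifier with the fixed protocol
#'
#' Mini-batch Adam with the step learning-rate schedule; after every epoch
#' the test set is evaluated and training terminates early once test accuracy
#' exceeds the configured threshold. Deterministic given the config seed.
#'
#' @param model A `flexfrag_model`.
#' @param train_data,test_data Lists with `x` (matrix features x n, one
#'   sample per column) and `y` (integer class ids 1..n_classes).
#' @param config A `train_config`.
#' @param verbose Print per-epoch progress.
#' @return The trained model, with a `history` attribute (data frame: epoch,
#'   lr, loss, train-batch accuracy, test accuracy).
#' @export
train <- function(model, train_data, test_data, config = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "flexfrag_model"))
  X <- train_data$x; y <- as.integer(train_data$y)
  if (!ncol(X) || !length(y)) stop("empty training data")
  ncheck <- tryCatch(model_forward(model, X[, 1, drop = FALSE]),
                     error = function(e)
                       stop("feature shape does not match the model: ",
                            conditionMessage(e), call. = FALSE))
  if (nrow(ncheck) != model$n_classes) stop("model/class mismatch")
  hist <- list()
  .with_seed(config$seed, {
    t_adam <- 0L
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_at_epoch(config, epoch)
      ord <- sample.int(ncol(X))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_correct <- 0
      for (b in batches) {
        logits <- model_forward(model, X[, b, drop = FALSE], training = TRUE)
        sc <- .softmax_ce(logits, y[b])
        ep_loss <- ep_loss + sc$loss * length(b)
        ep_correct <- ep_correct + sum(max.col(t(logits), "first") == y[b])
        .model_backward(model, sc$grad)
        t_adam <- t_adam + 1L
        .adam_step(model, lr, config$beta1, config$beta2, 1e-8, t_adam)
      }
      ev <- evaluate(model, test_data)
      hist[[epoch + 1L]] <- data.frame(
        epoch = epoch, lr = lr, loss = ep_loss / ncol(X),
        train_acc = 100 * ep_correct / ncol(X), test_acc = ev$accuracy)
      if (verbose)
        message(sprintf("epoch %3d lr %.2e loss %.4f train %.1f%% test %.1f%%",
                        epoch, lr, ep_loss / ncol(X),
                        100 * ep_correct / ncol(X), ev$accuracy))
      if (ev$accuracy > config$early_stop_acc) break
    }
  })
  attr(model, "history") <- do.call(rbind, hist)
  model
}

#' Evaluate a classifier: accuracy and confusion matrix
#'
#' @param model A `flexfrag_model`.
#' @param data List with `x` (matrix features x n, one sample per column) and
#'   `y` (integer labels 1..C); an optional `codes` element names the classes.
#' @param batch_size Forward batch size.
#' @return List: `accuracy` (percent, 100 * trace/total) and `confusion`
#'   (C x C integer matrix, rows = true classes).
#' @export
evaluate <- function(model, data, batch_size = 256L) {
  X <- data$x; y <- as.integer(data$y)
  if (!ncol(X)) stop("empty evaluation data")
  C <- model$n_classes
  pred <- integer(ncol(X))
  for (b in split(seq_len(ncol(X)), ceiling(seq_len(ncol(X)) / batch_size))) {
    logits <- model_forward(model, X[, b, drop = FALSE], training = FALSE)
    pred[b] <- max.col(t(logits), "first")
  }
  cm <- matrix(0L, C, C)
  for (i in seq_along(y)) cm[y[i], pred[i]] <- cm[y[i], pred[i]] + 1L
  if (!is.null(data$codes)) dimnames(cm) <- list(data$codes, data$codes)
  list(accuracy = 100 * sum(diag(cm)) / sum(cm), confusion = cm)
}

#' Lump a 400-class dipeptide confusion matrix per position
#'
#' Each dipeptide class is an ordered 2-tuple of residue codes; this
#' marginalizes the 400 x 400 confusion matrix to a 20 x 20 matrix for one
#' tuple position by summing over the other. Counts are conserved.
#'
#' @param matrix 400 x 400 confusion matrix whose row/column names are
#'   6-letter class codes (rows = true).
#' @param position 1 (N-terminal residue) or 2 (C-terminal residue).
#' @return 20 x 20 matrix with 3-letter code dimnames.
#' @export
lump_dual_confusion <- function(matrix, position = 1L) {
  if (nrow(matrix) != 400L || ncol(matrix) != 400L)
    stop("expected a 400 x 400 dipeptide confusion matrix")
  codes <- rownames(matrix)
  if (is.null(codes)) stop("matrix must carry 6-letter code dimnames")
  pos_code <- if (position == 1L) substr(codes, 1, 3) else substr(codes, 4, 6)
  out <- matrix(0, 20, 20, dimnames = list(.AA3, .AA3))
  ri <- match(pos_code, .AA3)
  ci <- match(if (position == 1L) substr(colnames(matrix), 1, 3)
              else substr(colnames(matrix), 4, 6), .AA3)
  for (i in seq_len(400))
    for (j in seq_len(400))
      out[ri[i], ci[j]] <- out[ri[i], ci[j]] + matrix[i, j]
  out
}
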