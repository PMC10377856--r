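# Compact convolutional classifier, implemented in full (forward, backprop,
# SGD) so the harness runs on a single CPU with no deep-learning framework.
#
# Architecture ("compact_cnn"): conv 3x3 (F1 filters) -> ReLU -> 2x2 mean
# pool -> conv 3x3 (F2 filters) -> ReLU -> global average pooling -> linear
# head -> softmax, cross-entropy loss. Grad-CAM attaches to the second
# convolution's activations, the final spatial feature block.

# linear-index table mapping each 3x3xC patch to columns of an im2col matrix
im2col_index <- function(H, W, C, k = 3) {
  oh <- H - k + 1; ow <- W - k + 1
  orow <- rep(seq_len(oh), times = ow)
  ocol <- rep(seq_len(ow), each = oh)
  base <- (ocol - 1L) * H + orow                    # top-left linear index
  offs <- as.integer(rep(0:(k - 1), times = k) +
                       H * rep(0:(k - 1), each = k))
  idx <- outer(base, offs, "+")                     # (oh*ow) x k^2
  if (C > 1) {
    idx <- do.call(cbind, lapply(0:(C - 1), function(ch) idx + ch * H * W))
  }
  list(idx = idx, oh = oh, ow = ow)
}

im2col <- function(x, tab) matrix(x[tab$idx], nrow = nrow(tab$idx))

col2im <- function(dcol, tab, H, W, C) {
  dx <- numeric(H * W * C)
  for (j in seq_len(ncol(dcol))) {
    jj <- tab$idx[, j]
    dx[jj] <- dx[jj] + dcol[, j]
  }
  array(dx, c(H, W, C))
}

# 2x2 mean pool over an (oh*ow) x F activation matrix laid out column-major
mean_pool2 <- function(a_mat, oh, ow) {
  ph <- oh %/% 2; pw <- ow %/% 2
  F_ <- ncol(a_mat)
  a <- array(a_mat, c(oh, ow, F_))
  a <- a[seq_len(2 * ph), seq_len(2 * pw), , drop = FALSE]
  pooled <- (a[seq(1, 2 * ph, 2), seq(1, 2 * pw, 2), , drop = FALSE] +
             a[seq(2, 2 * ph, 2), seq(1, 2 * pw, 2), , drop = FALSE] +
             a[seq(1, 2 * ph, 2), seq(2, 2 * pw, 2), , drop = FALSE] +
             a[seq(2, 2 * ph, 2), seq(2, 2 * pw, 2), , drop = FALSE]) / 4
  list(p = pooled, ph = ph, pw = pw)
}

unpool2 <- function(dp, oh, ow) {
  ph <- dim(dp)[1]; pw <- dim(dp)[2]; F_ <- dim(dp)[3]
  da <- array(0, c(oh, ow, F_))
  for (dr in 0:1) for (dc in 0:1) {
    da[seq(1 + dr, 2 * ph, 2), seq(1 + dc, 2 * pw, 2), ] <- dp / 4
  }
  da
}

#' Training configuration for the compact CNN harness
#'
#' Defaults follow the transfer-learning recipe: batch size 16, 50 epochs,
#' initial learning rate 0.001 reduced by a factor of 0.1 every 7 epochs,
#' cross-entropy loss. The `smoke` preset shrinks this to a CPU-scale
#' configuration (small inputs, few epochs) used throughout the tests.
#'
#' @param architecture `"compact_cnn"` (the only implemented backbone).
#' @param filters Integer pair: channels of the two conv layers.
#' @param input_size Side length images are resized to before training.
#' @param batch_size,epochs,lr,lr_decay_factor,lr_decay_every,seed Training
#'   hyperparameters.
#' @param freeze_features Train only the linear head on fixed random
#'   convolutional features.
#' @return A `train_config` list.
#' @export
train_config <- function(architecture = "compact_cnn", filters = c(8, 16),
                         input_size = 64, batch_size = 16, epochs = 50,
                         lr = 0.001, lr_decay_factor = 0.1,
                         lr_decay_every = 7, freeze_features = FALSE,
                         seed = 1) {
  if (!identical(architecture, "compact_cnn")) {
    stop("unknown architecture '", architecture,
         "'; this harness implements 'compact_cnn'")
  }
  stopifnot(length(filters) == 2, all(filters >= 1), input_size >= 12,
            batch_size >= 1, epochs >= 0, lr > 0,
            lr_decay_factor > 0, lr_decay_every >= 1)
  structure(list(architecture = architecture, filters = as.integer(filters),
                 input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 loss = "cross_entropy",
                 freeze_features = freeze_features, seed = as.integer(seed)),
            class = "train_config")
}

#' Reduced smoke-test configuration
#'
#' The CPU-scale recipe used throughout the test suite: 32-pixel inputs, a
#' frozen convolutional backbone (only the linear head trains), 20 epochs at
#' learning rate 0.1.
#'
#' @param ... Overrides passed to [train_config()].
#' @export
smoke_config <- function(...) {
  args <- utils::modifyList(
    list(input_size = 32, epochs = 20, lr = 0.1, batch_size = 16,
         lr_decay_every = 15, freeze_features = TRUE),
    list(...))
  do.call(train_config, args)
}

#' Learning rate at a (0-based) epoch under the step decay schedule
#'
#' `lr * factor^floor(epoch / every)`: with the defaults, epochs 0-6 train
#' at 0.001 and epoch 7 drops to 0.0001.
#'
#' @param cfg A [train_config()].
#' @param epoch 0-based epoch index.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay_factor^(epoch %/% cfg$lr_decay_every)
}

init_cnn_params <- function(cfg, n_classes) {
  F1 <- cfg$filters[1]; F2 <- cfg$filters[2]
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  # small positive biases keep fewer ReLU units dead at initialization
  list(W1 = he(27, F1), b1 = rep(0.05, F1),
       W2 = he(9 * F1, F2), b2 = rep(0.05, F2),
       Wd = he(F2, n_classes) / sqrt(2), bd = numeric(n_classes),
       # feature standardization (an affine layer with fixed constants,
       # estimated once on the training set before the first update)
       f_mu = numeric(F2), f_sd = rep(1, F2))
}

cnn_forward <- function(x, par, tabs, keep = FALSE) {
  X1 <- im2col(x, tabs$t1)
  Z1 <- sweep(X1 %*% par$W1, 2, par$b1, "+")
  A1 <- pmax(Z1, 0)
  pl <- mean_pool2(A1, tabs$t1$oh, tabs$t1$ow)
  X2 <- im2col(pl$p, tabs$t2)
  Z2 <- sweep(X2 %*% par$W2, 2, par$b2, "+")
  A2 <- pmax(Z2, 0)
  g <- colMeans(A2)
  gs <- (g - par$f_mu) / par$f_sd
  logits <- as.numeric(gs %*% par$Wd + par$bd)
  out <- list(logits = logits, g = g, gs = gs)
  if (keep) out <- c(out, list(X1 = X1, Z1 = Z1, pl = pl, X2 = X2,
                               Z2 = Z2, A2 = A2))
  out
}

cnn_backward <- function(x, y_onehot, par, tabs, fwd, freeze = FALSE) {
  p <- exp(fwd$logits - max(fwd$logits))
  p <- p / sum(p)
  dlog <- p - y_onehot
  gr <- list(Wd = outer(fwd$gs, dlog), bd = dlog)
  if (!freeze) {
    n2 <- nrow(fwd$A2)
    dG <- as.numeric(par$Wd %*% dlog) / par$f_sd
    dA2 <- matrix(rep(dG / n2, each = n2), n2)
    dZ2 <- dA2 * (fwd$Z2 > 0)
    gr$W2 <- crossprod(fwd$X2, dZ2)
    gr$b2 <- colSums(dZ2)
    dX2 <- dZ2 %*% t(par$W2)
    dP <- col2im(dX2, tabs$t2, fwd$pl$ph, fwd$pl$pw, ncol(fwd$Z1))
    dA1 <- unpool2(dP, tabs$t1$oh, tabs$t1$ow)
    dZ1 <- matrix(dA1, ncol = ncol(fwd$Z1)) * (fwd$Z1 > 0)
    gr$W1 <- crossprod(fwd$X1, dZ1)
    gr$b1 <- colSums(dZ1)
  }
  list(grads = gr, loss = -sum(y_onehot * log(pmax(p, 1e-12))))
}

# normalize input to an input_size x input_size x 3 [0,1] array
prep_input <- function(img, input_size) {
  a <- if (max(img, na.rm = TRUE) > 1.5) img / 255 else img
  a <- array(as.numeric(a), dim = dim(img))
  if (!all(dim(a)[1:2] == input_size)) {
    a <- resize_array(a, c(input_size, input_size))
  }
  a
}

load_training_data <- function(data, input_size) {
  if (is.data.frame(data)) {
    x <- lapply(data$file, read_image_png)
    y <- data$label
  } else {
    x <- data$x
    y <- data$y
  }
  list(x = lapply(x, prep_input, input_size = input_size),
       y = as.character(y))
}

#' Train the compact CNN classifier
#'
#' Minibatch SGD with cross-entropy loss and the step learning-rate decay of
#' [lr_at_epoch()]. With `epochs = 0` the randomly initialized model is
#' returned untrained (evaluation still runs). With
#' `cfg$freeze_features = TRUE` only the linear head is trained on fixed
#' random convolutional features.
#'
#' @param cfg A [train_config()].
#' @param data Either a manifest data frame with columns `file` and `label`,
#'   or a list with `x` (list of `H x W x 3` arrays in `[0,1]` or 0..255)
#'   and `y` (labels).
#' @return A `cnn_classifier`: parameters, class levels, config and a
#'   `history` data frame (per-epoch mean loss and training accuracy).
#' @export
train_classifier <- function(cfg, data) {
  td <- load_training_data(data, cfg$input_size)
  classes <- sort(unique(td$y))
  if (length(classes) < 2) stop("training data must contain at least 2 classes")
  y_idx <- match(td$y, classes)
  n <- length(td$x)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(cfg$seed)
  par <- init_cnn_params(cfg, length(classes))
  s <- cfg$input_size
  tabs <- list(t1 = im2col_index(s, s, 3))
  pooled <- c((s - 2) %/% 2, (s - 2) %/% 2)
  tabs$t2 <- im2col_index(pooled[1], pooled[2], cfg$filters[1])
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  if (cfg$epochs > 0) {
    # estimate the feature standardization on the training set once
    g0 <- t(vapply(td$x, function(img) cnn_forward(img, par, tabs)$g,
                   numeric(cfg$filters[2])))
    par$f_mu <- colMeans(g0)
    # floor keeps near-constant (dead) features from amplifying gradients
    par$f_sd <- pmax(apply(g0, 2, stats::sd), 1e-3)
    frozen_feats <- if (cfg$freeze_features) {
      sweep(sweep(g0, 2, par$f_mu), 2, par$f_sd, "/")
    }
    for (ep in seq_len(cfg$epochs)) {
      lr <- lr_at_epoch(cfg, ep - 1)
      ord <- sample(n)
      tot_loss <- 0; correct <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1, n)]
        acc <- NULL
        for (i in batch) {
          if (cfg$freeze_features) {
            gs <- frozen_feats[i, ]
            logits <- as.numeric(gs %*% par$Wd + par$bd)
            fwd <- list(logits = logits, gs = gs)
          } else {
            fwd <- cnn_forward(td$x[[i]], par, tabs, keep = TRUE)
          }
          oh <- as.numeric(seq_along(classes) == y_idx[i])
          bk <- cnn_backward(td$x[[i]], oh, par, tabs, fwd,
                             freeze = cfg$freeze_features)
          tot_loss <- tot_loss + bk$loss
          correct <- correct + (which.max(fwd$logits) == y_idx[i])
          if (is.null(acc)) acc <- bk$grads
          else for (nm in names(bk$grads)) acc[[nm]] <- acc[[nm]] + bk$grads[[nm]]
        }
        for (nm in names(acc)) {
          # elementwise gradient clipping keeps the standardization-scaled
          # backbone gradients from destabilizing small-batch SGD
          g_upd <- pmin(pmax(acc[[nm]] / length(batch), -1), 1)
          par[[nm]] <- par[[nm]] - lr * g_upd
        }
      }
      history <- rbind(history, data.frame(epoch = ep, loss = tot_loss / n,
                                           accuracy = correct / n))
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  structure(list(par = par, classes = classes, cfg = cfg, tabs = tabs,
                 history = history),
            class = "cnn_classifier")
}

#' @export
print.cnn_classifier <- function(x, ...) {
  cat(sprintf("<cnn_classifier> %s (%d+%d filters), classes: %s, %d epochs trained\n",
              x$cfg$architecture, x$cfg$filters[1], x$cfg$filters[2],
              paste(x$classes, collapse = "/"), nrow(x$history)))
  invisible(x)
}

#' Predict classes or probabilities for new images
#'
#' @param object A trained `cnn_classifier`.
#' @param newdata Manifest data frame (`file`, optionally `label`) or list
#'   with `x`.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @export
predict.cnn_classifier <- function(object, newdata, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  td <- if (is.data.frame(newdata)) {
    list(x = lapply(lapply(newdata$file, read_image_png), prep_input,
                    input_size = object$cfg$input_size))
  } else {
    list(x = lapply(newdata$x, prep_input, input_size = object$cfg$input_size))
  }
  probs <- t(vapply(td$x, function(img) {
    lg <- cnn_forward(img, object$par, object$tabs)$logits
    p <- exp(lg - max(lg)); p / sum(p)
  }, numeric(length(object$classes))))
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs)], levels = object$classes)
}

#' Grad-CAM heatmap for a single image
#'
#' Class-gradient-weighted average of the final convolutional feature maps,
#' rectified, bilinearly upsampled to the input size and min-max normalized
#' to `[0, 1]`. If every gradient-weighted activation is zero the heatmap is
#' all zeros and carries attribute `degenerate = TRUE`.
#'
#' @param model A `cnn_classifier`.
#' @param image `H x W x 3` array (8-bit or `[0,1]`).
#' @param class Class label to explain; defaults to the predicted class.
#' @return `H x W` heatmap matrix in `[0, 1]` (H, W = input size).
#' @export
grad_cam <- function(model, image, class = NULL) {
  x <- prep_input(image, model$cfg$input_size)
  fwd <- cnn_forward(x, model$par, model$tabs, keep = TRUE)
  ci <- if (is.null(class)) which.max(fwd$logits)
        else match(class, model$classes)
  if (is.na(ci)) stop("unknown class: ", class)
  n2 <- nrow(fwd$A2)
  # mean spatial gradient per channel (the standardization is affine, so it
  # only rescales the class gradient)
  alpha <- (model$par$Wd[, ci] / model$par$f_sd) / n2
  cam <- pmax(as.numeric(fwd$A2 %*% alpha), 0)
  h2 <- model$tabs$t2$oh; w2 <- model$tabs$t2$ow
  cam_m <- matrix(cam, h2, w2)
  up <- resize_array(array(cam_m, c(h2, w2, 1)),
                     c(model$cfg$input_size, model$cfg$input_size))[, , 1]
  rng <- range(up)
  if (rng[2] - rng[1] < 1e-12) {
    out <- matrix(0, nrow(up), ncol(up))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (up - rng[1]) / (rng[2] - rng[1])
}
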