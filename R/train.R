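# Training loop: focal Tversky objective, AdamW, minimum-validation-loss
# checkpoint selection.

#' Training configuration
#'
#' Defaults follow the reference protocol: batch size 16, AdamW with
#' learning rate 1e-3 and weight decay 1e-4, 50 epochs, checkpoint selection
#' by minimum validation loss.
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate AdamW learning rate (> 0).
#' @param weight_decay Decoupled weight decay.
#' @param epochs Number of epochs (>= 1).
#' @param seed Integer seed driving shuffling (weight initialization is
#'   seeded separately when the network is built).
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, learning_rate = 1e-3,
                         weight_decay = 1e-4, epochs = 50L, seed = 1L) {
  if (batch_size < 1 || epochs < 1 || learning_rate <= 0) {
    stop("invalid training configuration", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size),
                 optimizer = "adamw", learning_rate = learning_rate,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 seed = as.integer(seed)), class = "train_config")
}

stack_batch <- function(items, idx) {
  h <- nrow(items[[1]]); w <- ncol(items[[1]])
  array(unlist(items[idx], use.names = FALSE), c(h, w, 1L, length(idx)))
}

adamw_step <- function(params, grads, opt, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * ((opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps) +
              wd * params[[nm]])
  }
  list(params = params, opt = opt)
}

# aggregate focal Tversky loss over a set, in inference mode, from pooled
# soft counts
set_loss <- function(net, images, masks, params, batch_size, window) {
  s_tp <- s_fp <- s_fn <- 0
  n <- length(images)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- apply_window(stack_batch(images, idx), window)
    t <- stack_batch(masks, idx)
    pr <- sigmoid(net_forward(net, x, train = FALSE)$logits)
    tp <- sum(pr * t)
    s_tp <- s_tp + tp
    s_fp <- s_fp + sum(pr) - tp
    s_fn <- s_fn + sum(t) - tp
  }
  ti <- (s_tp + params$epsilon) /
    (s_tp + params$alpha * s_fp + params$beta * s_fn + params$epsilon)
  (1 - ti)^params$gamma
}

#' Train a segmentation network
#'
#' Runs mini-batch gradient descent with AdamW on the focal Tversky loss.
#' After every epoch the aggregate loss on the validation set is computed in
#' inference mode; the returned fit carries the weights of the epoch with
#' the minimum validation loss (earliest epoch on ties) together with the
#' full per-epoch loss trace.  Single-threaded runs with equal seeds are
#' bit-reproducible.
#'
#' @param net An `orbitnet` from [build_proposed()] or [build_segnet()].
#' @param train_set,val_set Lists with `images` (HU matrices) and `masks`
#'   (logical matrices) as returned by [load_dataset()]; both non-empty.
#' @param config A [train_config()].
#' @param tversky A [tversky_params()].
#' @param window [window_spec()] used to normalize images.
#' @return Object of class `orbitnet_fit`: `net` (best weights), `trace`
#'   (data frame epoch / train_loss / val_loss), `best_epoch`, `config`.
#' @export
train_network <- function(net, train_set, val_set, config = train_config(),
                          tversky = tversky_params(),
                          window = window_spec()) {
  stopifnot(inherits(net, "orbitnet"), inherits(config, "train_config"))
  n <- length(train_set$images)
  if (n == 0L || length(val_set$images) == 0L) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  opt <- list(t = 0L,
              m = lapply(net$params, function(p) array(0, dim = dim(p) %||%
                                                         length(p))),
              v = lapply(net$params, function(p) array(0, dim = dim(p) %||%
                                                         length(p))))
  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
  best <- list(val = Inf, epoch = NA_integer_, params = net$params,
               state = net$state)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      step_losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1, n)]
        x <- apply_window(stack_batch(train_set$images, idx), window)
        t <- stack_batch(train_set$masks, idx)
        fwd <- net_forward(net, x, train = TRUE, keep_cache = TRUE)
        net$state <- fwd$state
        pr <- sigmoid(fwd$logits)
        ft <- focal_tversky_grad(pr, t, tversky)
        if (!is.finite(ft$loss)) {
          stop("non-finite training loss at epoch ", epoch, call. = FALSE)
        }
        step_losses <- c(step_losses, ft$loss)
        grads <- net_backward(net, fwd, ft$grad * pr * (1 - pr))
        upd <- adamw_step(net$params, grads, opt, config$learning_rate,
                          config$weight_decay)
        net$params <- upd$params
        opt <- upd$opt
      }
      val_loss <- set_loss(net, val_set$images, val_set$masks, tversky,
                           config$batch_size, window)
      if (!is.finite(val_loss)) {
        stop("non-finite validation loss at epoch ", epoch, call. = FALSE)
      }
      trace <- rbind(trace, data.frame(epoch = epoch,
                                       train_loss = mean(step_losses),
                                       val_loss = val_loss))
      if (val_loss < best$val) {
        best <- list(val = val_loss, epoch = epoch, params = net$params,
                     state = net$state)
      }
    }
  })
  net$params <- best$params
  net$state <- best$state
  structure(list(net = net, trace = trace, best_epoch = best$epoch,
                 best_val_loss = best$val, config = config,
                 tversky = tversky, window = window),
            class = "orbitnet_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.orbitnet_fit <- function(x, ...) {
  cat(sprintf("Fitted %s network: %d epochs, best epoch %d (val loss %.4g)\n",
              x$net$variant, nrow(x$trace), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
plot.orbitnet_fit <- function(x, ...) {
  graphics::matplot(x$trace$epoch, cbind(x$trace$train_loss,
                                         x$trace$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "focal Tversky loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
predict.orbitnet_fit <- function(object, newdata, ...) {
  predict(object$net, newdata, window = object$window, ...)
}

#' @export
residuals.orbitnet_fit <- function(object, newdata, ...) {
  # signed per-pixel error of the probability map against the mask
  pr <- predict(object$net, newdata$image %||% newdata, ...)
  if (!is.null(newdata$mask)) pr - as.numeric(newdata$mask) else pr
}

#' Evaluate a network on a test set
#'
#' Applies sigmoid and threshold binarization to each test image, computes
#' pixel-wise confusion counts against the ground-truth mask, and reports
#' per-image Dice and IoU plus their means over the set.
#'
#' @param net An `orbitnet` or `orbitnet_fit`.
#' @param test_set List with `images`, `masks` and optionally `ids`.
#' @param threshold Binarization threshold (default 0.5).
#' @param window [window_spec()] for image normalization.
#' @return Object of class `seg_eval`: data frame `per_image` with columns
#'   `id, dice, iou`, and scalars `mean_dice`, `mean_iou`.
#' @export
evaluate_network <- function(net, test_set, threshold = 0.5,
                             window = window_spec()) {
  if (inherits(net, "orbitnet_fit")) {
    window <- net$window
    net <- net$net
  }
  n <- length(test_set$images)
  if (n == 0L) stop("test set is empty", call. = FALSE)
  ids <- test_set$ids %||% as.character(seq_len(n))
  dice_v <- iou_v <- numeric(n)
  for (i in seq_len(n)) {
    x <- apply_window(stack_batch(test_set$images, i), window)
    pr <- sigmoid(net_forward(net, x, train = FALSE)$logits)
    pred <- binarize(pr, threshold)
    cc <- confusion_counts(pred[, , 1, 1], test_set$masks[[i]])
    dice_v[i] <- dice_coef(cc)
    iou_v[i] <- iou(cc)
  }
  structure(list(per_image = data.frame(id = ids, dice = dice_v,
                                        iou = iou_v,
                                        stringsAsFactors = FALSE),
                 mean_dice = mean(dice_v), mean_iou = mean(iou_v)),
            class = "seg_eval")
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("Segmentation evaluation over %d images: mean Dice %.4f, mean IoU %.4f\n",
              nrow(x$per_image), x$mean_dice, x$mean_iou))
  invisible(x)
}
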