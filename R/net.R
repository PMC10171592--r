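# The encoder-decoder segmentation network and its SegNet-style baseline.
#
# Encoder: five blocks of (conv -> BN -> ReLU) x {2,2,3,3,3}, each followed
# by 2x2 max pooling with recorded argmax indices.  The pre-pool output of
# block b is retained as the skip feature at scale 1/2^(b-1), so skips exist
# at scales 1, 1/2, 1/4, 1/8 and 1/16 of the input; the bottleneck after the
# fifth pooling sits at 1/32.
#
# Decoder: five symmetric blocks.  Block b first max-unpools with the
# encoder's level-b indices, then (proposed variant) concatenates the
# level-b skip feature along channels, then applies (conv -> BN -> ReLU)
# layers mirroring the encoder widths; the final convolution of block 1 maps
# to `num_classes` logits with no BN/ReLU.  The baseline ("segnet") is
# identical except that no skip features are concatenated: the decoder sees
# only the pooling indices.

#' Network configuration
#'
#' @param in_channels Input channels (default 1, grayscale CT).
#' @param num_classes Output channels / segmentation targets (default 1,
#'   one network per tissue with a sigmoid head).
#' @param conv_counts Convolutions per block, length 5 (default
#'   `c(2, 2, 3, 3, 3)`).
#' @param widths Channels per block, length 5 (default
#'   `c(64, 128, 256, 512, 512)`, the VGG-16 family used by SegNet).
#' @param kernel Odd convolution kernel size (default 3; stride 1,
#'   zero-padding preserves the spatial size).
#' @param skip_fusion Skip fusion mode; only `"concatenate"` is defined.
#' @return Object of class `net_config`.
#' @export
net_config <- function(in_channels = 1L, num_classes = 1L,
                       conv_counts = c(2L, 2L, 3L, 3L, 3L),
                       widths = c(64L, 128L, 256L, 512L, 512L),
                       kernel = 3L, skip_fusion = "concatenate") {
  if (length(conv_counts) != 5L || length(widths) != 5L) {
    stop("conv_counts and widths must have length 5", call. = FALSE)
  }
  if (any(widths <= 0) || any(conv_counts < 1)) {
    stop("widths and conv_counts must be positive", call. = FALSE)
  }
  if (kernel %% 2 != 1) stop("kernel size must be odd", call. = FALSE)
  skip_fusion <- match.arg(skip_fusion, "concatenate")
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 conv_counts = as.integer(conv_counts),
                 widths = as.integer(widths), kernel = as.integer(kernel),
                 pool = 2L, skip_fusion = skip_fusion),
            class = "net_config")
}

# Flat list of conv-layer descriptors for one variant.
plan_layers <- function(config, skip) {
  cc <- config$conv_counts
  w <- config$widths
  layers <- list()
  add <- function(name, cin, cout, bn = TRUE, relu = TRUE, block, stage) {
    layers[[length(layers) + 1L]] <<- list(name = name, cin = cin,
                                           cout = cout, bn = bn,
                                           relu = relu, block = block,
                                           stage = stage)
  }
  for (b in 1:5) {
    for (j in seq_len(cc[b])) {
      cin <- if (j > 1) w[b] else if (b == 1) config$in_channels else w[b - 1]
      add(sprintf("enc%d_conv%d", b, j), cin, w[b], block = b,
          stage = "encoder")
    }
  }
  ch <- w[5]  # channels entering the decoder (bottleneck)
  for (b in 5:1) {
    cin_block <- ch + if (skip) w[b] else 0L
    for (j in seq_len(cc[b])) {
      cin <- if (j == 1) cin_block else w[b]
      if (b == 1 && j == cc[b]) {
        add(sprintf("dec%d_conv%d", b, j),
            if (cc[b] == 1) cin_block else w[b], config$num_classes,
            bn = FALSE, relu = FALSE, block = b, stage = "decoder")
      } else {
        cout <- if (j == cc[b] && b > 1) w[b - 1] else w[b]
        add(sprintf("dec%d_conv%d", b, j), cin, cout, block = b,
            stage = "decoder")
      }
    }
    if (b > 1) ch <- w[b - 1]
  }
  layers
}

init_params <- function(layers, k) {
  params <- list()
  state <- list()
  for (L in layers) {
    fan_in <- k * k * L$cin
    params[[paste0(L$name, ".w")]] <-
      array(rnorm(k * k * L$cin * L$cout, 0, sqrt(2 / fan_in)),
            c(k, k, L$cin, L$cout))
    params[[paste0(L$name, ".b")]] <- numeric(L$cout)
    if (L$bn) {
      params[[paste0(L$name, ".gamma")]] <- rep(1, L$cout)
      params[[paste0(L$name, ".beta")]] <- numeric(L$cout)
      state[[L$name]] <- list(mean = numeric(L$cout), var = rep(1, L$cout))
    }
  }
  list(params = params, state = state)
}

new_orbitnet <- function(config, variant, seed) {
  layers <- plan_layers(config, skip = identical(variant, "proposed"))
  ini <- with_seed(seed, init_params(layers, config$kernel))
  structure(list(config = config, variant = variant, layers = layers,
                 params = ini$params, state = ini$state),
            class = "orbitnet")
}

#' Build the segmentation networks
#'
#' `build_proposed()` constructs the skip-connected encoder-decoder network
#' (un-pooling plus five-scale skip concatenation); `build_segnet()`
#' constructs the baseline with the identical encoder whose decoder uses
#' only the pooling indices.  Weights are He-initialized under `seed`; batch
#' norm starts at identity.
#'
#' With the default configuration the two networks hold 34,935,169 and
#' 29,442,433 trainable parameters respectively (34 vs. 29 million,
#' truncated): the difference is exactly the widened first convolution of
#' each decoder block that absorbs the concatenated skip channels.
#'
#' @param config A [net_config()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `orbitnet`.
#' @examples
#' net <- build_proposed(net_config(widths = c(2, 3, 4, 5, 5)))
#' count_parameters(net)
#' @export
build_proposed <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  new_orbitnet(config, "proposed", seed)
}

#' @rdname build_proposed
#' @export
build_segnet <- function(config = net_config(), seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  new_orbitnet(config, "segnet", seed)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars: convolution weights and biases plus
#' batch-norm scale/shift.  Running batch-norm statistics are not trainable
#' and are not counted.
#'
#' @param net An `orbitnet`.
#' @return Integer count.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "orbitnet"))
  sum(vapply(net$params, length, integer(1)))
}

#' @export
print.orbitnet <- function(x, ...) {
  cat(sprintf("Orbital segmentation network (%s variant)\n",
              x$variant))
  cat(sprintf("  encoder/decoder blocks: 5 + 5; conv counts %s\n",
              paste(x$config$conv_counts, collapse = "-")))
  cat(sprintf("  widths: %s; kernel %dx%d; pool 2x2\n",
              paste(x$config$widths, collapse = ", "), x$config$kernel,
              x$config$kernel))
  cat(sprintf("  skip connections: %s\n",
              if (x$variant == "proposed")
                "five scales (1, 1/2, 1/4, 1/8, 1/16), concatenated"
              else "none (pooling indices only)"))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.orbitnet <- function(object, ...) {
  rows <- lapply(object$layers, function(L) {
    n <- object$config$kernel^2 * L$cin * L$cout + L$cout +
      if (L$bn) 2L * L$cout else 0L
    data.frame(layer = L$name, stage = L$stage, block = L$block,
               in_ch = L$cin, out_ch = L$cout, bn = L$bn,
               params = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.orbitnet", "data.frame")
  attr(out, "variant") <- object$variant
  out
}

#' @export
print.summary.orbitnet <- function(x, ...) {
  cat(sprintf("Layer summary (%s variant), %s parameters total\n",
              attr(x, "variant"), format(sum(x$params), big.mark = ",")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
coef.orbitnet <- function(object, ...) object$params

# ---------------------------------------------------------------------------
# forward / backward

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# gradient of unpool w.r.t. its input: gather at the recorded indices
unpool_gather <- function(g, idx) {
  d_out <- dim(g)
  d_in <- dim(idx)
  hw_out <- d_out[1] * d_out[2]
  hw_in <- d_in[1] * d_in[2]
  planes <- d_in[3] * d_in[4]
  off <- rep((seq_len(planes) - 1L) * hw_out, each = hw_in)
  gp <- g[as.vector(idx) + 1L + off]
  dim(gp) <- d_in
  gp
}

conv_bn_relu_fwd <- function(L, params, state, x, train) {
  w <- params[[paste0(L$name, ".w")]]
  y <- conv_forward(x, w, params[[paste0(L$name, ".b")]])
  cache <- list(x = x, conv_out = NULL, mu = NULL, inv_std = NULL)
  if (L$bn) {
    cache$conv_out <- y
    bn <- bn_forward(y, params[[paste0(L$name, ".gamma")]],
                     params[[paste0(L$name, ".beta")]], state[[L$name]],
                     train = train)
    y <- bn$y
    cache$mu <- bn$mu
    cache$inv_std <- bn$inv_std
    state[[L$name]] <- bn$running
  }
  if (L$relu) y <- relu_forward(y)
  cache$y <- y
  list(y = y, cache = cache, state = state)
}

conv_bn_relu_bwd <- function(L, params, cache, g) {
  grads <- list()
  if (L$relu) g <- relu_backward(cache$y, g)
  if (L$bn) {
    bnb <- bn_backward(cache$conv_out, g, params[[paste0(L$name, ".gamma")]],
                       cache$mu, cache$inv_std)
    grads[[paste0(L$name, ".gamma")]] <- bnb$dgamma
    grads[[paste0(L$name, ".beta")]] <- bnb$dbeta
    g <- bnb$gx
  }
  cb <- conv_backward(cache$x, params[[paste0(L$name, ".w")]], g)
  grads[[paste0(L$name, ".w")]] <- cb$gw
  grads[[paste0(L$name, ".b")]] <- cb$gb
  list(g = cb$gx, grads = grads)
}

# Full forward pass.  Returns logits; with keep_cache = TRUE also every
# intermediate needed by net_backward, and with train = TRUE batch-norm uses
# (and updates) batch statistics.
net_forward <- function(net, x, train = FALSE, keep_cache = FALSE) {
  x <- as_feature_array(x)
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop("input spatial size must be divisible by 32", call. = FALSE)
  }
  if (d[3] != net$config$in_channels) {
    stop("input channel count does not match the network", call. = FALSE)
  }
  skip <- identical(net$variant, "proposed")
  by_block <- split(seq_along(net$layers),
                    vapply(net$layers, function(L)
                      paste(L$stage, L$block), character(1)))
  caches <- list()
  skips <- vector("list", 5)
  idxs <- vector("list", 5)
  sizes <- vector("list", 5)
  state <- net$state
  y <- x
  for (b in 1:5) {
    for (li in by_block[[paste("encoder", b)]]) {
      L <- net$layers[[li]]
      r <- conv_bn_relu_fwd(L, net$params, state, y, train)
      y <- r$y; state <- r$state
      if (keep_cache) caches[[L$name]] <- r$cache
    }
    skips[[b]] <- y
    sizes[[b]] <- dim(y)[1:2]
    p <- pool_with_indices(y)
    y <- p$y
    idxs[[b]] <- p$idx
  }
  for (b in 5:1) {
    y <- unpool(y, idxs[[b]], sizes[[b]])
    if (keep_cache) caches[[sprintf("dec%d_unpool_dim", b)]] <- dim(y)
    if (skip) y <- cat_channels(y, skips[[b]])
    for (li in by_block[[paste("decoder", b)]]) {
      L <- net$layers[[li]]
      r <- conv_bn_relu_fwd(L, net$params, state, y, train)
      y <- r$y; state <- r$state
      if (keep_cache) caches[[L$name]] <- r$cache
    }
  }
  out <- list(logits = y, state = state)
  if (keep_cache) {
    out$caches <- caches
    out$idxs <- idxs
    out$sizes <- sizes
  }
  out
}

# Backward pass from d loss / d logits; returns gradients named like params.
net_backward <- function(net, fwd, grad_logits) {
  skip <- identical(net$variant, "proposed")
  by_block <- split(seq_along(net$layers),
                    vapply(net$layers, function(L)
                      paste(L$stage, L$block), character(1)))
  grads <- list()
  skip_grads <- vector("list", 5)
  g <- grad_logits
  for (b in 1:5) {
    for (li in rev(by_block[[paste("decoder", b)]])) {
      L <- net$layers[[li]]
      r <- conv_bn_relu_bwd(L, net$params, fwd$caches[[L$name]], g)
      grads[names(r$grads)] <- r$grads
      g <- r$g
    }
    if (skip) {
      up_c <- fwd$caches[[sprintf("dec%d_unpool_dim", b)]][3]
      skip_grads[[b]] <- g[, , up_c + seq_len(dim(g)[3] - up_c), ,
                           drop = FALSE]
      g <- g[, , seq_len(up_c), , drop = FALSE]
    }
    g <- unpool_gather(g, fwd$idxs[[b]])
  }
  for (b in 5:1) {
    gpre <- unpool(g, fwd$idxs[[b]], fwd$sizes[[b]])
    if (skip) gpre <- gpre + skip_grads[[b]]
    g <- gpre
    for (li in rev(by_block[[paste("encoder", b)]])) {
      L <- net$layers[[li]]
      r <- conv_bn_relu_bwd(L, net$params, fwd$caches[[L$name]], g)
      grads[names(r$grads)] <- r$grads
      g <- r$g
    }
  }
  grads
}

#' Segment an image with a network
#'
#' Runs the network in inference mode (batch-norm running statistics,
#' sigmoid head) on one image or a batch.
#'
#' @param object An `orbitnet` (typically the `$net` of a fitted
#'   [train_network()] result).
#' @param newdata A `ct_slice`, an HU matrix, an already-normalized
#'   \[0, 1\] matrix, or a `(H, W, C, N)` array.  HU inputs are normalized
#'   with `window`.
#' @param type `"prob"` for sigmoid probabilities, `"mask"` for the
#'   binarized mask at `threshold`, `"logits"` for raw outputs.
#' @param window [window_spec()] applied to HU inputs.
#' @param threshold Binarization threshold for `type = "mask"`.
#' @param ... Unused.
#' @return Array of dim `(H, W, num_classes, N)`.
#' @export
predict.orbitnet <- function(object, newdata, type = c("prob", "mask",
                                                       "logits"),
                             window = window_spec(), threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.list(newdata) && inherits(newdata$image, "ct_slice")) {
    newdata <- newdata$image  # a render_slice() result
  }
  if (inherits(newdata, "ct_slice")) newdata <- newdata$hu
  x <- as_feature_array(newdata)
  if (min(x) < 0 || max(x) > 1) x <- apply_window(x, window)
  logits <- net_forward(object, x, train = FALSE)$logits
  switch(type,
         logits = logits,
         prob = sigmoid(logits),
         mask = binarize(sigmoid(logits), threshold))
}

# ---------------------------------------------------------------------------
# checkpoints

#' Save / load a network checkpoint
#'
#' A checkpoint is a single RDS file holding the architecture configuration,
#' the variant, all weights and the batch-norm running statistics, plus any
#' metadata supplied in `extra` (for instance the training trace).
#'
#' @param net An `orbitnet`.
#' @param path File path.
#' @param extra Optional named list stored alongside the weights.
#' @return `load_checkpoint()` returns a list with `net` and `extra`.
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  stopifnot(inherits(net, "orbitnet"))
  saveRDS(list(config = unclass(net$config), variant = net$variant,
               params = net$params, state = net$state, extra = extra),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  config <- do.call(net_config, obj$config[c("in_channels", "num_classes",
                                             "conv_counts", "widths",
                                             "kernel", "skip_fusion")])
  net <- new_orbitnet(config, obj$variant, seed = 1L)
  net$params <- obj$params
  net$state <- obj$state
  list(net = net, extra = obj$extra)
}
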