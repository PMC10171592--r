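# Layer primitives.  Feature maps are numeric 4-D arrays dim (H, W, C, N);
# single images / masks are accepted as 2-D matrices and promoted.

as_feature_array <- function(x) {
  if (is.matrix(x)) {
    dim(x) <- c(dim(x), 1L, 1L)
  } else if (length(dim(x)) == 3L) {
    dim(x) <- c(dim(x), 1L)
  } else if (length(dim(x)) != 4L) {
    stop("expected a 2-D matrix or a (H, W, C, N) array", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

conv_forward <- function(x, w, b) .conv2d_fwd(x, w, b)
conv_backward <- function(x, w, gy) .conv2d_bwd(x, w, gy)

#' Max pooling with argmax indices
#'
#' Non-overlapping 2x2, stride-2 max pooling that additionally records, for
#' every pooling window, where its maximum sat in the input plane.  The
#' decoder's un-pooling layer ([unpool()]) uses these indices to put each
#' value back in exactly that place, which is what lets the decoder restore
#' sharp boundaries without any trainable upsampling parameters.
#'
#' Ties within a window resolve to the first maximum in row-major scan order
#' of the window.
#'
#' @param x A 2-D matrix or a numeric array of dim `(H, W, C, N)` with even
#'   `H` and `W`.
#' @return A list with `y`, the pooled array of dim `(H/2, W/2, C, N)`, and
#'   `idx`, an integer array of the same dim holding 0-based linear positions
#'   `h + H*w` into the corresponding input plane.
#' @examples
#' p <- pool_with_indices(matrix(c(1, 3, 2, 4), 2, 2))
#' p$y[1, 1, 1, 1]  # 4
#' @seealso [unpool()]
#' @export
pool_with_indices <- function(x) {
  x <- as_feature_array(x)
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("spatial dimensions must be even for 2x2 pooling", call. = FALSE)
  }
  .maxpool2_fwd(x)
}

#' Max un-pooling
#'
#' Restores a pooled feature map to `out_size` by placing every value at the
#' argmax location recorded by [pool_with_indices()] and zero-filling all
#' other positions.  The sum of the output equals the sum of the input.
#'
#' @param pooled Pooled array (2-D matrix or `(H, W, C, N)` array).
#' @param idx Index array as returned by [pool_with_indices()]; must have the
#'   same dim as `pooled`.
#' @param out_size Integer vector `c(H, W)` of the target spatial size.
#' @return Array of dim `(H, W, C, N)`.
#' @examples
#' p <- pool_with_indices(matrix(c(1, 3, 2, 4), 2, 2))
#' unpool(p$y, p$idx, c(2, 2))[, , 1, 1]  # 4 back at its original position
#' @export
unpool <- function(pooled, idx, out_size) {
  pooled <- as_feature_array(pooled)
  if (!is.array(idx)) dim(idx) <- dim(pooled)
  if (!identical(dim(idx), dim(pooled))) {
    stop("idx and pooled must have identical dimensions", call. = FALSE)
  }
  .unpool2(pooled, idx, as.integer(out_size[1]), as.integer(out_size[2]))
}

relu_forward <- function(x) {
  x[x < 0] <- 0
  x
}

relu_backward <- function(y, gy) {
  gy[y <= 0] <- 0
  gy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Batch normalization over (H, W, N) per channel, with affine parameters.
# In training mode batch statistics are used and running statistics updated
# by exponential moving average; in inference mode the running statistics
# are used.
bn_forward <- function(x, gamma, beta, running, train = TRUE,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- hw * N
  dim(x) <- c(hw, C, N)
  if (train) {
    s1 <- rowSums(colSums(x))            # per-channel sum
    mu <- s1 / m
    s2 <- rowSums(colSums(x * x))
    v <- s2 / m - mu^2
    v[v < 0] <- 0
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv_std <- 1 / sqrt(v + eps)
  scale <- gamma * inv_std
  shift <- beta - mu * scale
  y <- x * rep(scale, each = hw) + rep(shift, each = hw)
  dim(y) <- d
  list(y = y, mu = mu, inv_std = inv_std, running = running)
}

bn_backward <- function(x, gy, gamma, mu, inv_std) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- hw * N
  dim(x) <- c(hw, C, N)
  dim(gy) <- c(hw, C, N)
  xhat <- (x - rep(mu, each = hw)) * rep(inv_std, each = hw)
  dgamma <- rowSums(colSums(gy * xhat))
  dbeta <- rowSums(colSums(gy))
  gx <- rep(gamma * inv_std / m, each = hw) *
    (m * gy - rep(dbeta, each = hw) - xhat * rep(dgamma, each = hw))
  dim(gx) <- d
  list(gx = gx, dgamma = dgamma, dbeta = dbeta)
}
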