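test_that("pooling takes the window maximum and records its position", {
  p <- pool_with_indices(matrix(c(1, 3, 2, 4), 2, 2))  # column-major fill
  expect_equal(p$y[1, 1, 1, 1], 4)
  expect_equal(p$idx[1, 1, 1, 1], 3L)  # bottom-right: h=1, w=1 -> 1 + 2*1
  # constant window: tie resolves to first position in row-major scan order
  pc <- pool_with_indices(matrix(5, 2, 2))
  expect_equal(pc$y[1, 1, 1, 1], 5)
  expect_equal(pc$idx[1, 1, 1, 1], 0L)  # top-left
  # a tie along the top row picks (0,0) before (0,1)
  pt <- pool_with_indices(matrix(c(7, 1, 7, 2), 2, 2))
  expect_equal(pt$idx[1, 1, 1, 1], 0L)
})

test_that("pooling matches a brute-force window-scan oracle", {
  for (seed in 1:5) {
    m <- matrix(with_seed_rnorm(64, seed), 8, 8)
    p <- pool_with_indices(m)
    expect_equal(p$y[, , 1, 1], pool_oracle(m))
  }
})

test_that("unpool restores values at argmax positions and zeros elsewhere", {
  for (seed in 1:5) {
    m <- matrix(with_seed_rnorm(64, seed + 10), 8, 8)
    p <- pool_with_indices(m)
    u <- unpool(p$y, p$idx, c(8, 8))[, , 1, 1]
    nz <- which(u != 0)
    expect_length(nz, 16)                 # one survivor per window
    expect_equal(u[nz], m[nz])            # survivors carry the input value
    expect_equal(sum(u), sum(p$y))        # mass preserved
  }
  # definition example: single value placed top-right of its 2x2 window
  u <- unpool(matrix(5, 1, 1), array(2L, c(1, 1, 1, 1)), c(2, 2))
  expect_equal(u[, , 1, 1], matrix(c(0, 0, 5, 0), 2, 2))
  expect_equal(unpool(matrix(0, 1, 1), array(0L, c(1, 1, 1, 1)), c(2, 2)),
               array(0, c(2, 2, 1, 1)))
})

test_that("pool-unpool-pool is a fixed point on non-negative inputs", {
  # in the network pooling always follows ReLU, so inputs are >= 0; there
  # the zero-filled positions can never beat the restored window maximum
  for (seed in 1:20) {
    set.seed(seed + 20)
    m <- matrix(runif(256), 16, 16)
    p1 <- pool_with_indices(m)
    u <- unpool(p1$y, p1$idx, c(16, 16))
    p2 <- pool_with_indices(u)
    expect_identical(p2$y, p1$y)
  }
})

test_that("pooling and unpooling reject malformed inputs", {
  expect_error(pool_with_indices(matrix(0, 3, 4)), "even")
  expect_error(pool_with_indices(matrix(0, 4, 3)), "even")
  p <- pool_with_indices(matrix(1, 4, 4))
  bad <- p$idx
  bad[1] <- 99L
  expect_error(unpool(p$y, bad, c(4, 4)), "out of range")
  expect_error(unpool(p$y, p$idx[1, , , , drop = FALSE], c(4, 4)),
               "identical dimensions")
})

test_that("batch norm normalizes per channel and its gradient is exact", {
  set.seed(31)
  x <- array(rnorm(6 * 8 * 3 * 4, mean = 2, sd = 3), c(6, 8, 3, 4))
  gamma <- c(1.5, 0.5, 2)
  beta <- c(0.1, -0.2, 0)
  run <- list(mean = numeric(3), var = rep(1, 3))
  fw <- orbitseg:::bn_forward(x, gamma, beta, run, train = TRUE)
  for (c in 1:3) {
    v <- fw$y[, , c, ]
    expect_equal(mean(v), beta[c], tolerance = 1e-10)
    expect_equal(sd(v) * sqrt(length(v) - 1) / sqrt(length(v)),
                 gamma[c], tolerance = 1e-4)
  }
  gy <- array(rnorm(length(x)), dim(x))
  bw <- orbitseg:::bn_backward(x, gy, gamma, fw$mu, fw$inv_std)
  f <- function(xv) {
    xa <- array(xv, dim(x))
    sum(orbitseg:::bn_forward(xa, gamma, beta, run, train = TRUE)$y * gy)
  }
  eps <- 1e-5
  for (i in c(1, 77, 400)) {
    x1 <- as.vector(x); x1[i] <- x1[i] + eps
    x2 <- as.vector(x); x2[i] <- x2[i] - eps
    fd <- (f(x1) - f(x2)) / (2 * eps)
    expect_equal(bw$gx[i], fd, tolerance = 1e-5)
  }
})
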