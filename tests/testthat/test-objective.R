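test_that("the Tversky index is 1 on perfect overlap and 0 on none", {
  set.seed(1)
  t <- matrix(rbinom(100, 1, 0.4), 10)
  expect_equal(soft_tversky_index(t, t), 1, tolerance = 1e-6)
  expect_equal(soft_tversky_index(matrix(0, 10, 10), t), 0,
               tolerance = 1e-6)
  expect_equal(focal_tversky_loss(t, t), 0, tolerance = 1e-5)
  expect_equal(focal_tversky_loss(matrix(0, 10, 10), t), 1,
               tolerance = 1e-5)
  # both empty: smoothing makes the index 1, the loss 0
  z <- matrix(0, 4, 4)
  expect_equal(soft_tversky_index(z, z), 1)
  expect_equal(focal_tversky_loss(z, z), 0)
})

test_that("hand-counted example: TP=2, FP=1, FN=2 at alpha=beta=0.5", {
  target <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 0, 0, 1, 0, 0, 0)
  pars <- tversky_params(alpha = 0.5, beta = 0.5, gamma = 1)
  expect_equal(soft_tversky_index(pred, target, pars), 2 / 3.5,
               tolerance = 1e-6)
  expect_equal(focal_tversky_loss(pred, target, pars), 1 - 2 / 3.5,
               tolerance = 1e-6)
})

test_that("alpha=beta=0.5, gamma=1 reduces to 1 - soft Dice", {
  pars <- tversky_params(alpha = 0.5, beta = 0.5, gamma = 1,
                         epsilon = 1e-12)
  for (seed in 1:20) {
    set.seed(seed)
    p <- matrix(runif(144), 12)
    t <- matrix(rbinom(144, 1, runif(1, 0.1, 0.9)), 12)
    soft_dice <- 2 * sum(p * t) / (sum(p) + sum(t))
    expect_equal(focal_tversky_loss(p, t, pars), 1 - soft_dice,
                 tolerance = 1e-10)
  }
})

test_that("the loss is bounded and strictly decreasing in the index", {
  set.seed(2)
  t <- matrix(rbinom(256, 1, 0.3), 16)
  pars <- tversky_params()
  # blend from pure noise to the target: overlap rises, loss must fall
  noise <- matrix(runif(256), 16)
  losses <- sapply(seq(0, 1, by = 0.25), function(a) {
    focal_tversky_loss(a * t + (1 - a) * noise * 0.5, t, pars)
  })
  expect_true(all(losses >= 0 & losses <= 1))
  expect_true(all(diff(losses) < 0))
  # direct functional form: loss = (1 - TI)^gamma
  p <- matrix(runif(256), 16)
  expect_equal(focal_tversky_loss(p, t, pars),
               (1 - soft_tversky_index(p, t, pars))^pars$gamma)
})

test_that("the analytic loss gradient matches finite differences", {
  for (pars in list(tversky_params(),
                    tversky_params(alpha = 0.5, beta = 0.5, gamma = 1))) {
    set.seed(3)
    p <- matrix(runif(64, 0.05, 0.95), 8)
    t <- matrix(rbinom(64, 1, 0.4), 8)
    g <- orbitseg:::focal_tversky_grad(p, t, pars)
    expect_equal(g$loss, focal_tversky_loss(p, t, pars))
    eps <- 1e-7
    for (i in c(1, 17, 40, 64)) {
      p1 <- p; p1[i] <- p1[i] + eps
      p2 <- p; p2[i] <- p2[i] - eps
      fd <- (focal_tversky_loss(p1, t, pars) -
               focal_tversky_loss(p2, t, pars)) / (2 * eps)
      expect_equal(g$grad[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("invalid inputs and parameters are rejected", {
  expect_error(soft_tversky_index(matrix(0.5, 2, 2), matrix(0, 2, 3)),
               "shape")
  expect_error(soft_tversky_index(matrix(2, 2, 2), matrix(1, 2, 2)),
               "\\[0, 1\\]")
  expect_error(soft_tversky_index(matrix(0.5, 2, 2), matrix(0.5, 2, 2)),
               "binary")
  expect_error(tversky_params(alpha = -1), "alpha")
  expect_error(tversky_params(gamma = 0), "gamma")
  expect_error(tversky_params(epsilon = 0), "epsilon")
})
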