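test_that("default architecture reproduces the published parameter counts", {
  p <- build_proposed()
  s <- build_segnet()
  expect_identical(count_parameters(p), 34935169L)
  expect_identical(count_parameters(s), 29442433L)
  expect_identical(count_parameters(p) %/% 1000000L, 34L)
  expect_identical(count_parameters(s) %/% 1000000L, 29L)
  expect_lt(count_parameters(s), count_parameters(p))
})

test_that("parameter counting follows the closed-form layer formula", {
  # one 3x3 conv 1 -> 1 with bias costs 10 scalars; build the smallest
  # config and check the total against an independent sum over the plan
  cfg <- tiny_config()
  net <- build_proposed(cfg)
  expected <- sum(vapply(net$layers, function(L) {
    9L * L$cin * L$cout + L$cout + if (L$bn) 2L * L$cout else 0L
  }, integer(1)))
  expect_identical(count_parameters(net), expected)
  s <- summary(net)
  expect_equal(sum(s$params), expected)
  w <- net$params[["enc1_conv1.w"]]
  expect_equal(length(w) + length(net$params[["enc1_conv1.b"]]),
               9 * 1 * 2 + 2)
})

test_that("forward output matches the input spatial size", {
  cfg <- tiny_config()
  net <- build_proposed(cfg, seed = 2)
  x <- array(runif(128 * 128), c(128, 128, 1, 1))
  f <- orbitseg:::net_forward(net, x, keep_cache = TRUE)
  expect_equal(dim(f$logits), c(128, 128, 1, 1))
  # bottleneck after five poolings sits at 1/32: 4x4 for a 128 input
  expect_equal(dim(f$idxs[[5]])[1:2], c(4L, 4L))
  # skip features live at scales 1, 1/2, 1/4, 1/8, 1/16
  expect_equal(vapply(f$sizes, `[`, integer(1), 1),
               c(128L, 64L, 32L, 16L, 8L))
  # full clinical resolution passes through unchanged
  x512 <- array(runif(512 * 512), c(512, 512, 1, 1))
  f512 <- orbitseg:::net_forward(net, x512)
  expect_equal(dim(f512$logits), c(512, 512, 1, 1))
  # SegNet baseline has the identical shape contract
  ns <- build_segnet(cfg, seed = 2)
  expect_equal(dim(orbitseg:::net_forward(ns, x)$logits), c(128, 128, 1, 1))
})

test_that("inputs not divisible by 32 are rejected at forward time", {
  net <- build_proposed(tiny_config())
  expect_error(orbitseg:::net_forward(net, matrix(0, 100, 100)),
               "divisible by 32")
  expect_error(predict(net, matrix(0.5, 96, 100)), "divisible by 32")
})

test_that("weight initialization is seed-deterministic", {
  a <- build_proposed(tiny_config(), seed = 9)
  b <- build_proposed(tiny_config(), seed = 9)
  c <- build_proposed(tiny_config(), seed = 10)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("zeroing the skip pathways reproduces the SegNet forward", {
  cfg <- tiny_config()
  seg <- build_segnet(cfg, seed = 4)
  prop <- build_proposed(cfg, seed = 5)
  # transplant SegNet weights; skip input channels get zero weights so the
  # concatenated features cannot contribute
  for (nm in names(seg$params)) prop$params[[nm]][] <- 0
  for (nm in names(seg$params)) {
    ps <- seg$params[[nm]]
    if (grepl("^dec.\\_conv1\\.w$", nm)) {
      prop$params[[nm]][, , seq_len(dim(ps)[3]), ] <- ps
    } else {
      prop$params[[nm]] <- ps
    }
  }
  x <- array(runif(64 * 64), c(64, 64, 1, 2))
  expect_equal(orbitseg:::net_forward(prop, x)$logits,
               orbitseg:::net_forward(seg, x)$logits, tolerance = 1e-12)
})

test_that("gradients reach every trainable parameter and match finite differences", {
  cfg <- tiny_config()
  net <- build_proposed(cfg, seed = 6)
  set.seed(7)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  t <- array(rbinom(32 * 32 * 2, 1, 0.3), c(32, 32, 1, 2))
  pars <- tversky_params()
  fwd <- orbitseg:::net_forward(net, x, train = TRUE, keep_cache = TRUE)
  pr <- orbitseg:::sigmoid(fwd$logits)
  ft <- orbitseg:::focal_tversky_grad(pr, t, pars)
  grads <- orbitseg:::net_backward(net, fwd, ft$grad * pr * (1 - pr))
  expect_setequal(names(grads), names(net$params))
  # every weight tensor receives signal (conv biases feeding BN are the
  # only analytically-zero gradients, since BN subtracts the mean)
  wnames <- grep("\\.(w|gamma|beta)$", names(grads), value = TRUE)
  expect_true(all(vapply(wnames, function(n) any(grads[[n]] != 0),
                         logical(1))))
  loss_of <- function(n) {
    lg <- orbitseg:::net_forward(n, x, train = TRUE)$logits
    focal_tversky_loss(orbitseg:::sigmoid(lg), t, pars)
  }
  eps <- 1e-5
  set.seed(8)
  for (nm in sample(wnames, 6)) {
    i <- sample(length(net$params[[nm]]), 1)
    n1 <- net; n1$params[[nm]][i] <- n1$params[[nm]][i] + eps
    n2 <- net; n2$params[[nm]][i] <- n2$params[[nm]][i] - eps
    fd <- (loss_of(n1) - loss_of(n2)) / (2 * eps)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-3)
  }
})

test_that("checkpoints round-trip weights, config and predictions", {
  net <- build_proposed(slim_config(), seed = 11)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, f, extra = list(tissue = "eyeball"))
  back <- load_checkpoint(f)
  expect_identical(back$net$params, net$params)
  expect_identical(back$net$config, net$config)
  expect_identical(back$extra$tissue, "eyeball")
  x <- matrix(runif(64 * 64), 64, 64)
  expect_equal(predict(back$net, x), predict(net, x))
})

test_that("predict handles CT slices, HU matrices and prob arrays", {
  net <- build_proposed(tiny_config(), seed = 12)
  sl <- render_slice(phantom_spec(image_size = 64), "axial1", seed = 1)
  p1 <- predict(net, sl)                      # ct_slice
  p2 <- predict(net, sl$image$hu)             # raw HU matrix
  p3 <- predict(net, apply_window(sl$image$hu))  # pre-normalized
  expect_equal(p1, p2)
  expect_equal(p1, p3)
  expect_true(all(p1 >= 0 & p1 <= 1))
  m <- predict(net, sl, type = "mask")
  expect_true(all(m %in% c(0L, 1L)))
})
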