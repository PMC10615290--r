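test_that("residual blocks implement inner(x) + x", {
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  p0 <- zeroed_resblock(3L, 3L)
  expect_equal(residual_block(x, p0, training = TRUE), x)

  p <- residual_block_params(3L, 3L, seed = 2L)
  out <- residual_block(x, p, training = TRUE)
  expect_equal(dim(out), dim(x))

  # channel mismatch engages the 1x1 projection
  pm <- residual_block_params(3L, 5L, seed = 2L)
  out5 <- residual_block(x, pm, training = TRUE)
  expect_equal(dim(out5), c(6, 6, 5))
})

test_that("residual block gradients match finite differences", {
  set.seed(8)
  p <- residual_block_params(1L, 1L, seed = 8L)
  x <- array(rnorm(16), c(4, 4, 1, 1))
  dout <- array(rnorm(16), c(4, 4, 1, 1))
  fw <- sparus:::resblock_fw(p, x, TRUE)
  bw <- sparus:::resblock_bw(p, fw$cache, dout)
  eps <- 1e-6
  num <- numeric(16)
  for (i in 1:16) {
    x1 <- x; x1[i] <- x[i] + eps
    x2 <- x; x2[i] <- x[i] - eps
    num[i] <- (sum(sparus:::resblock_fw(p, x1, TRUE)$out * dout) -
                 sum(sparus:::resblock_fw(p, x2, TRUE)$out * dout)) /
      (2 * eps)
  }
  expect_equal(as.numeric(bw$dx), num, tolerance = 1e-6)
  # the identity path contributes dout itself: zero inner weights make
  # the Jacobian exactly the identity
  p0 <- zeroed_resblock(1L, 1L)
  fw0 <- sparus:::resblock_fw(p0, x, TRUE)
  bw0 <- sparus:::resblock_bw(p0, fw0$cache, dout)
  expect_equal(bw0$dx, dout)
})

test_that("sub-pixel upscaling is a value-preserving bijection", {
  x <- array(seq_len(2 * 2 * 4), c(2, 2, 4))
  expect_identical(subpixel_upscale(x, 1L), x)
  up <- subpixel_upscale(x, 2L)
  expect_equal(dim(up), c(4, 4, 1))
  expect_setequal(as.vector(up), as.vector(x))

  x4 <- array(rnorm(3 * 5 * 8 * 2), c(3, 5, 8, 2))
  up4 <- sparus:::pixel_shuffle(x4, 2L)
  expect_identical(sparus:::pixel_unshuffle(up4, 2L), x4)
  expect_error(subpixel_upscale(array(0, c(2, 2, 3)), 2L),
               class = "sparus_validation_error")
})

test_that("runet builds are seeded and shape-conserving", {
  cfg <- runet_config(depth = 3L, base_channels = 4L, seed = 21L)
  m1 <- build_runet(cfg)
  m2 <- build_runet(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_runet(runet_config(depth = 3L, base_channels = 4L,
                                 seed = 22L))
  expect_false(identical(m1$params, m3$params))

  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  out <- sparus:::runet_fw(m1, x)$out
  expect_equal(dim(out), dim(x))
  expect_true(all(is.finite(out)))
  err <- tryCatch(sparus:::runet_fw(m1, array(0, c(60, 60, 1, 1))),
                  error = function(e) conditionMessage(e))
  expect_match(err, "divisible by 2\\^depth")
  expect_error(runet_config(depth = 0L), class = "sparus_validation_error")
  expect_error(runet_config(loss_weights = list(pixel = 0, perceptual = 0)),
               class = "sparus_validation_error")
})

test_that("the training loss satisfies its contracts", {
  m <- build_runet(runet_config(depth = 1L, base_channels = 2L))
  a <- matrix(runif(64), 8)
  expect_equal(runet_loss(a, a, list(pixel = 1, perceptual = 0.1),
                          m$perceptual), 0)
  # zero perceptual weight reduces to pure pixel L1
  b <- matrix(runif(64), 8)
  expect_equal(runet_loss(a, b, list(pixel = 1, perceptual = 0)),
               mean(abs(a - b)))
  set.seed(9)
  for (i in 1:20) {
    p <- matrix(runif(64), 8); q <- matrix(runif(64), 8)
    expect_gte(runet_loss(p, q, list(pixel = 1, perceptual = 0.1),
                          m$perceptual), 0)
  }
  expect_error(runet_loss(a, matrix(0, 4, 4), list(pixel = 1,
                                                   perceptual = 0)),
               class = "sparus_validation_error")
})

test_that("loss gradients match finite differences", {
  m <- build_runet(runet_config(depth = 1L, base_channels = 2L))
  set.seed(12)
  pred <- array(runif(64), c(8, 8, 1, 1))
  targ <- array(runif(64), c(8, 8, 1, 1))
  w <- list(pixel = 1, perceptual = 0.1)
  g <- runet_loss(pred, targ, w, m$perceptual, grad = TRUE)
  eps <- 1e-6
  for (i in sample(64, 8)) {
    p1 <- pred; p1[i] <- pred[i] + eps
    p2 <- pred; p2[i] <- pred[i] - eps
    num <- (runet_loss(p1, targ, w, m$perceptual) -
              runet_loss(p2, targ, w, m$perceptual)) / (2 * eps)
    expect_equal(g$dpred[i], num, tolerance = 1e-5)
  }
})

test_that("training is reproducible, optional, and can memorize", {
  set.seed(13)
  sp <- matrix(as.integer(pmin(pmax(
    round(127 + 60 * sin(outer(1:16, 1:16, `+`) / 3)), 0), 255)), 16)
  dn <- matrix(as.integer(pmin(pmax(
    round(127 + 60 * cos(outer(1:16, 1:16, `-`) / 4)), 0), 255)), 16)
  data <- list(sparse = list(sp), dense = list(dn),
               split = list(train = 1L, val = integer()))

  # epochs = 0 is a no-op
  m0 <- build_runet(runet_config(depth = 2L, base_channels = 4L,
                                 epochs = 0L, seed = 14L))
  expect_identical(train_runet(m0, data)$params, m0$params)

  # 200 steps on a single pair memorizes it
  cfg <- runet_config(depth = 2L, base_channels = 4L, epochs = 200L,
                      batch_size = 1L, learning_rate = 1e-3, seed = 14L)
  m <- train_runet(build_runet(cfg), data)
  expect_lt(tail(m$history$train_loss, 1),
            0.1 * m$history$train_loss[1])

  # same seed, same curves
  m2 <- train_runet(build_runet(cfg), data)
  expect_identical(m$history, m2$history)
  expect_error(train_runet(build_runet(cfg),
                           list(sparse = list(sp), dense = list(dn),
                                split = list(train = integer(),
                                             val = integer()))),
               class = "sparus_validation_error")
})

test_that("prediction clamps to 8-bit and checkpoints round-trip", {
  cfg <- runet_config(depth = 2L, base_channels = 4L, epochs = 2L,
                      batch_size = 2L, seed = 15L)
  set.seed(16)
  mk <- function() matrix(as.integer(runif(32 * 32, 0, 255)), 32)
  data <- list(sparse = lapply(1:4, function(i) mk()),
               dense = lapply(1:4, function(i) mk()),
               split = list(train = 1:3, val = 4L))
  m <- train_runet(build_runet(cfg), data)
  sp <- mk()
  out <- predict(m, sp)
  expect_equal(dim(out), dim(sp))
  expect_true(all(out >= 0L & out <= 255L))
  expect_true(is.integer(out))

  path <- file.path(tempdir(), "ckpt.h5")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(predict(back, sp), out)
  expect_equal(back$history, m$history)
  expect_identical(back$config, m$config)
  unlink(path)

  # history respects the epoch budget
  expect_lte(nrow(m$history), cfg$epochs)
})
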