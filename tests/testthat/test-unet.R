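# Response network: architecture arithmetic, residual identity, training.

test_that("shape constraints are enforced and propagate through the network", {
  expect_error(networkSpec(5, 8, 100, 96), "divisible")
  sp <- networkSpec(3L, 8L, 64L, 64L)
  net <- buildNetwork(sp, seed = 2)
  x <- matrix(runif(64 * 64), 64, 64)
  out <- forwardNetwork(net, x)
  expect_identical(dim(out), c(64L, 64L))  # shape-propagation oracle
  expect_error(forwardNetwork(net, matrix(0, 32, 32)), "shape")
  # 256 x 192 at depth 5 pools to an 8 x 6 bottleneck
  expect_identical(c(256L, 192L) %/% 32L, c(8L, 6L))
})

test_that("zeroing the final projection makes the network the identity (residual output)", {
  sp <- networkSpec(2L, 4L, 32L, 24L)
  net <- buildNetwork(sp, seed = 3)
  nw <- length(net$weights)
  net$weights[[nw - 1]][] <- 0  # final 1x1 weights
  net$weights[[nw]][] <- 0     # final bias
  x <- matrix(runif(32 * 24), 32, 24)
  expect_equal(forwardNetwork(net, x), x, tolerance = 1e-6)
})

test_that("a small network overfits a single pair to near-zero MSE", {
  set.seed(44)
  x <- matrix(runif(64 * 48, 0, 1), 64, 48)
  y <- 0.9 * x + 0.05
  bundle <- new("DatasetBundle", inputs = list(x), targets = list(y),
                meta = data.frame(field = 1L), splitTrain = 1L,
                splitVal = integer(0), splitTest = integer(0), seed = 1L,
                pixelPitch = c(400 / 64, 400 / 64))
  m <- trainResponseNet(bundle, networkSpec(3L, 8L, 64L, 48L),
                        trainSpec(learningRate = 2e-3, batchSize = 1L,
                                  epochs = 400L, seed = 5L,
                                  doseScale = 1, tiScale = 1))
  lh <- lossHistory(m)
  expect_identical(nrow(lh), 400L)
  expect_true(all(is.finite(lh$train)))
  expect_lt(lh$train[400], 1e-5)  # overfit oracle
  # prediction applies the inverse scaling and clamps to >= 0
  pred <- predictTI(m, x)
  expect_s4_class(pred, "TransmissionImage")
  expect_equal(provenance(pred), "predicted")
  expect_lt(mean(abs(imageValues(pred) - y)), 5e-3)
})

test_that("training is deterministic for a fixed seed", {
  set.seed(9)
  xs <- lapply(1:4, function(i) matrix(runif(32 * 24), 32, 24))
  ys <- lapply(xs, function(x) 0.8 * x)
  bundle <- new("DatasetBundle", inputs = xs, targets = ys,
                meta = data.frame(field = 1:4), splitTrain = 1:3,
                splitVal = 4L, splitTest = integer(0), seed = 1L,
                pixelPitch = c(400 / 32, 400 / 32))
  run <- function() trainResponseNet(bundle, networkSpec(2L, 4L, 32L, 24L),
                                     trainSpec(learningRate = 1e-3,
                                               batchSize = 2L, epochs = 5L,
                                               seed = 11L))
  m1 <- run(); m2 <- run()
  expect_identical(lossHistory(m1), lossHistory(m2))
  expect_identical(m1@weights, m2@weights)
  expect_true(all(is.finite(lossHistory(m1)$val)) &&
                all(lossHistory(m1)$val >= 0))
})

test_that("scaling constants default to the training-split maxima and are stored", {
  xs <- lapply(1:3, function(i) matrix(i, 32, 24))
  ys <- lapply(1:3, function(i) matrix(2 * i, 32, 24))
  bundle <- new("DatasetBundle", inputs = xs, targets = ys,
                meta = data.frame(field = 1:3), splitTrain = 1:2,
                splitVal = integer(0), splitTest = 3L, seed = 1L,
                pixelPitch = c(400 / 32, 400 / 32))
  m <- trainResponseNet(bundle, networkSpec(2L, 4L, 32L, 24L),
                        trainSpec(epochs = 1L, batchSize = 2L))
  expect_equal(m@trainSpec@doseScale, 2)  # max over the training split only
  expect_equal(m@trainSpec@tiScale, 4)
})
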