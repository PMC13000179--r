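# small toy problem: a bright square blob on a dark background
toyData <- function(n, size = 16) {
  x <- array(0, c(size, size, 1, n))
  y <- array(0, c(size, size, 1, n))
  for (i in seq_len(n)) {
    r <- sample(2:(size - 6), 2)
    img <- matrix(0.2 + rnorm(size * size, sd = 0.02), size, size)
    img[r[1]:(r[1] + 4), r[2]:(r[2] + 4)] <- 0.8
    x[, , 1, i] <- pmin(pmax(img, 0), 1)
    y[r[1]:(r[1] + 4), r[2]:(r[2] + 4), 1, i] <- 1
  }
  list(x = x, y = y)
}

test_that("training loss is finite and decreases on a separable toy", {
  set.seed(401)
  td <- toyData(8)
  m <- buildSegModel(scheme = 3, inputSize = 16, widths = c(4, 6, 8))
  fit <- trainModel(m, td, config = trainConfig(epochs = 5, seed = 401,
                                                batchSize = 4))
  expect_true(all(is.finite(fit$stepLoss)))
  expect_lt(mean(tail(fit$stepLoss, 3)), mean(head(fit$stepLoss, 3)))
})

test_that("identical seeds give bitwise-identical loss curves", {
  set.seed(403); td <- toyData(8)
  set.seed(403); m1 <- buildSegModel(scheme = 1, inputSize = 16,
                                     widths = c(4, 6, 8))
  set.seed(403); m2 <- buildSegModel(scheme = 1, inputSize = 16,
                                     widths = c(4, 6, 8))
  cfg <- trainConfig(epochs = 2, seed = 11, batchSize = 4)
  f1 <- trainModel(m1, td, config = cfg)
  f2 <- trainModel(m2, td, config = cfg)
  expect_identical(f1$stepLoss, f2$stepLoss)
})

test_that("frozen quantum angles keep QPG kernels constant across steps", {
  set.seed(405)
  td <- toyData(8)
  m <- buildSegModel(scheme = 1, inputSize = 16, widths = c(4, 6, 8))
  k0 <- layerKernel(m@layers$encoder1)
  fit <- trainModel(m, td, config = trainConfig(epochs = 2, seed = 5,
                                                batchSize = 4,
                                                freezeQuantum = TRUE))
  expect_identical(layerKernel(fit$model@layers$encoder1), k0)
  # and classical parts still moved
  expect_false(identical(fit$model@layers$block1$W, m@layers$block1$W))
})

test_that("backprop through the hybrid model matches finite differences", {
  set.seed(407)
  m <- buildSegModel(scheme = 3, inputSize = 8, widths = c(2, 3, 4))
  # move biases and BN shifts off zero so no pre-activation sits exactly
  # at the ReLU kink (where the one-sided derivative convention and a
  # central difference legitimately disagree)
  params <- qpgnet:::.modelParams(m)
  for (nm in names(params)) {
    if (!is.null(params[[nm]]$b))
      params[[nm]]$b <- params[[nm]]$b + runif(length(params[[nm]]$b), 0.05, 0.2)
    if (!is.null(params[[nm]]$beta))
      params[[nm]]$beta <- params[[nm]]$beta + runif(length(params[[nm]]$beta), 0.05, 0.2)
  }
  m <- qpgnet:::.setModelParams(m, params)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  fw <- qpgnet:::.segForwardFull(m, x, keepCache = TRUE)
  ls <- qpgnet:::.segLoss(fw$prob, fw$logits, y, "bce_dice")
  gr <- qpgnet:::.segBackward(m, fw, ls$dLogits)
  lossAt <- function(model) {
    f <- qpgnet:::.segForwardFull(model, x, keepCache = FALSE,
                                  training = TRUE)
    qpgnet:::.segLoss(f$prob, f$logits, y, "bce_dice")$loss
  }
  h <- 1e-6
  params <- qpgnet:::.modelParams(m)
  for (nm in c("encoder1", "block2", "dblock1", "finalconv", "block1_bn")) {
    for (pn in names(params[[nm]])) {
      idxs <- sample(length(params[[nm]][[pn]]),
                     min(4, length(params[[nm]][[pn]])))
      for (i in idxs) {
        pu <- params; pu[[nm]][[pn]][i] <- pu[[nm]][[pn]][i] + h
        pd <- params; pd[[nm]][[pn]][i] <- pd[[nm]][[pn]][i] - h
        fd <- (lossAt(qpgnet:::.setModelParams(m, pu)) -
                 lossAt(qpgnet:::.setModelParams(m, pd))) / (2 * h)
        expect_equal(gr[[nm]][[pn]][i], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("degenerate training inputs abort with a diagnostic", {
  set.seed(409)
  m <- buildSegModel(scheme = 0, inputSize = 16, widths = c(4, 6, 8))
  expect_error(trainModel(m, list(x = array(0, c(16, 16, 1, 0)),
                                  y = array(0, c(16, 16, 1, 0)))),
               "empty")
  td <- toyData(4)
  td$x[1, 1, 1, 1] <- NaN
  expect_error(trainModel(m, td, config = trainConfig(epochs = 1, seed = 1,
                                                      batchSize = 4)),
               "non-finite loss")
})

test_that("a QPG layer recovers a realizable target kernel", {
  set.seed(411)
  target <- generateKernel(qpgLayerConfig(cIn = 4, cOut = 1, kH = 3))
  start <- qpgLayerConfig(cIn = 4, cOut = 1, kH = 3)
  fit <- fitQPGKernel(start, target, steps = 300, lr = 0.05)
  expect_lt(fit$maxError, 0.05)
  expect_lt(tail(fit$mseTrace, 1), head(fit$mseTrace, 1))
})

test_that("training configuration validates its inputs", {
  expect_error(trainConfig(lr = -1))
  expect_error(trainConfig(epochs = 0))
  cfg <- trainConfig()
  expect_equal(cfg$lr, 0.001)
  expect_equal(cfg$weightDecay, 5e-4)
  expect_identical(cfg$batchSize, 8L)
  expect_identical(cfg$epochs, 20L)
})
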