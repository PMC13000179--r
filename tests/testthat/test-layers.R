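test_that("QPGConv forward equals direct convolution with the exported kernel", {
  set.seed(71)
  for (trial in 1:10) {
    cIn <- sample(1:4, 1); cOut <- sample(1:4, 1)
    k <- sample(c(1, 3), 1)
    ly <- qpgConvLayer(cIn, cOut, k,
                       strategy = sample(c("sst", "rce", "lpp"), 1))
    x <- array(rnorm(6 * 6 * cIn * 2), c(6, 6, cIn, 2))
    out <- qpgConvForward(x, ly)
    ref <- naiveConv(x, layerKernel(ly), pad = (k - 1) / 2)
    expect_lt(max(abs(out - ref)), 1e-6)
  }
})

test_that("QPGConv basics: zero input, channel mismatch, 1x1 scaling", {
  set.seed(73)
  ly <- qpgConvLayer(2, 2, 3)
  expect_identical(max(abs(qpgConvForward(array(0, c(8, 8, 2, 1)), ly))), 0)
  expect_error(qpgConvForward(array(0, c(8, 8, 3, 1)), ly),
               "channel mismatch")
  ly1 <- qpgConvLayer(1, 1, 1)
  x <- array(rnorm(16), c(4, 4, 1, 1))
  w <- layerKernel(ly1)[1, 1, 1, 1]
  expect_equal(qpgConvForward(x, ly1), x * w, tolerance = 1e-12)
})

test_that("QPGAConv with a zero increment returns exactly the base convolution", {
  set.seed(79)
  base <- array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3))
  cfg <- qpgLayerConfig(cIn = 2, cOut = 1, kH = 3,
                        angles = matrix(0, 2, 9))   # 1-qubit VQCs, SST
  ly <- qpgaConvLayer(base, config = cfg)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  expect_identical(qpgaConvForward(x, ly),
                   qpgnet:::.convForward(x, base)$out)
})

test_that("QPGAConv with a zero base reduces to QPGConv", {
  set.seed(83)
  cfg <- qpgLayerConfig(cIn = 3, cOut = 2, kH = 3)
  lyA <- qpgaConvLayer(array(0, c(3, 2, 3, 3)), config = cfg)
  lyQ <- qpgConvLayer(3, 2, 3, config = cfg)
  x <- array(rnorm(6 * 6 * 3 * 1), c(6, 6, 3, 1))
  expect_equal(qpgaConvForward(x, lyA), qpgConvForward(x, lyQ),
               tolerance = 1e-12)
})

test_that("QPGAConv never exposes its base kernel as a trainable parameter", {
  set.seed(89)
  ly <- qpgaConvLayer(array(rnorm(36), c(2, 2, 3, 3)))
  p <- qpgnet:::.layerParams(ly)
  expect_named(p, "angles")
  # updating trainable parameters leaves the base untouched
  p$angles <- p$angles + 1
  ly2 <- qpgnet:::.setLayerParams(ly, p)
  expect_identical(ly2$base, ly$base)
})

test_that("ConvLoRA counts follow the per-position rank factorization", {
  expect_identical(convLoRAParamCount(64, 64, 3, 3, rank = 8), 9216L)
  expect_identical(convLoRAParamCount(64, 64, 3, 3, rank = 16), 18432L)
  expect_identical(convLoRAParamCount(4, 4, 1, 1, rank = 1), 8L)
  set.seed(97)
  ly <- convLoRALayer(array(0, c(4, 4, 1, 1)), rank = 1)
  expect_identical(length(ly$A) + length(ly$B),
                   as.integer(convLoRAParamCount(4, 4, 1, 1, rank = 1)))
})

test_that("ConvLoRA starts at the base kernel and moves with its factors", {
  set.seed(101)
  base <- array(rnorm(2 * 3 * 3 * 3), c(2, 3, 3, 3))
  ly <- convLoRALayer(base, rank = 2)
  expect_identical(layerKernel(ly), base)   # B initialized at zero
  ly$B[] <- rnorm(length(ly$B))
  W <- layerKernel(ly)
  for (kh in 1:3) for (kw in 1:3)
    expect_equal(W[, , kh, kw] - base[, , kh, kw],
                 t(ly$B[, , (kw - 1) * 3 + kh] %*% ly$A[, , (kw - 1) * 3 + kh]),
                 tolerance = 1e-12)
})

test_that("parameter-efficiency ordering holds at the 64->64 3x3 layer", {
  vqc <- countTrainable(allocateVQC(64, 64, 3, 3))$vqc
  expect_true(vqc < convLoRAParamCount(64, 64, 3, 3, rank = 8))
  expect_true(convLoRAParamCount(64, 64, 3, 3, rank = 8) <
                convLoRAParamCount(64, 64, 3, 3, rank = 16))
  expect_true(convLoRAParamCount(64, 64, 3, 3, rank = 16) <
                classicParamCount(64, 64, 3, 3))
})

test_that("convolution backward matches finite differences", {
  set.seed(103)
  x <- array(rnorm(5 * 5 * 2 * 2), c(5, 5, 2, 2))
  W <- array(rnorm(2 * 3 * 3 * 3), c(2, 3, 3, 3))
  b <- rnorm(3)
  fw <- qpgnet:::.convForward(x, W, b)
  dOut <- array(rnorm(length(fw$out)), dim(fw$out))
  bk <- qpgnet:::.convBackward(fw$cache, W, dOut)
  h <- 1e-6
  lossAt <- function(xx, WW, bb)
    sum(dOut * qpgnet:::.convForward(xx, WW, bb)$out)
  for (r in 1:5) {
    i <- sample(length(W), 1)
    Wu <- W; Wu[i] <- Wu[i] + h; Wd <- W; Wd[i] <- Wd[i] - h
    expect_equal(bk$dW[i], (lossAt(x, Wu, b) - lossAt(x, Wd, b)) / (2 * h),
                 tolerance = 1e-4)
    j <- sample(length(x), 1)
    xu <- x; xu[j] <- xu[j] + h; xd <- x; xd[j] <- xd[j] - h
    expect_equal(bk$dX[j], (lossAt(xu, W, b) - lossAt(xd, W, b)) / (2 * h),
                 tolerance = 1e-4)
  }
  bu <- b; bu[2] <- bu[2] + h; bd <- b; bd[2] <- bd[2] - h
  expect_equal(bk$db[2], (lossAt(x, W, bu) - lossAt(x, W, bd)) / (2 * h),
               tolerance = 1e-4)
})

test_that("batch normalization backward matches finite differences", {
  set.seed(107)
  ly <- qpgnet:::.bnLayer(3)
  ly$gamma <- runif(3, 0.5, 1.5); ly$beta <- rnorm(3, 0, 0.2)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  fw <- qpgnet:::.bnForward(ly, x, training = TRUE)
  dOut <- array(rnorm(length(fw$out)), dim(fw$out))
  bk <- qpgnet:::.bnBackward(ly, fw$cache, dOut)
  h <- 1e-6
  lossAtX <- function(xx) sum(dOut * qpgnet:::.bnForward(ly, xx, TRUE)$out)
  for (r in 1:5) {
    j <- sample(length(x), 1)
    xu <- x; xu[j] <- xu[j] + h; xd <- x; xd[j] <- xd[j] - h
    expect_equal(bk$dX[j], (lossAtX(xu) - lossAtX(xd)) / (2 * h),
                 tolerance = 1e-4)
  }
  lyG <- ly; lyG$gamma[2] <- lyG$gamma[2] + h
  lyG2 <- ly; lyG2$gamma[2] <- lyG2$gamma[2] - h
  fdG <- (sum(dOut * qpgnet:::.bnForward(lyG, x, TRUE)$out) -
            sum(dOut * qpgnet:::.bnForward(lyG2, x, TRUE)$out)) / (2 * h)
  expect_equal(bk$gamma[2], fdG, tolerance = 1e-4)
})

test_that("after one training step every allocated VQC has moved", {
  set.seed(109)
  cfg <- qpgLayerConfig(cIn = 3, cOut = 2, kH = 2)
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  ly <- qpgConvLayer(3, 2, 2, config = cfg)
  fw <- qpgnet:::.convForward(x, layerKernel(ly), NULL, 1L, NULL)
  dOut <- array(rnorm(length(fw$out)), dim(fw$out))
  bk <- qpgnet:::.convBackward(fw$cache, layerKernel(ly), dOut, needX = FALSE)
  g <- qpgnet:::.layerParamGrads(ly, bk$dW)
  # slice locality: every VQC column receives some gradient
  expect_true(all(colSums(abs(g$angles)) > 0))
})
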