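test_that("channel allocation follows the smaller-axis rule", {
  cases <- list(
    # cIn, cOut, kH, kW, nVQCs, qubits, axis
    list(512, 32, 2, 2, 128L, 9L, "output"),
    list(64, 256, 3, 3, 576L, 8L, "input"),
    list(64, 1, 3, 3, 9L, 6L, "output"),
    list(4, 4, 1, 1, 4L, 2L, "input")   # tie goes to the input axis
  )
  for (cs in cases) {
    p <- allocateVQC(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_identical(nVQCs(p), cs[[5]])
    expect_identical(qubitsPerVQC(p), cs[[6]])
    expect_identical(targetAxis(p), cs[[7]])
    expect_identical(valuesPerVQC(p), as.integer(max(cs[[1]], cs[[2]])))
  }
  expect_error(allocateVQC(0, 4, 3, 3), ">= 1")
  expect_error(allocateVQC(4, -1, 3, 3), ">= 1")
})

test_that("trainable-parameter ledgers reproduce the printed counts", {
  expect_identical(countTrainable(allocateVQC(64, 1, 3, 3))$vqc, 108L)
  expect_identical(countTrainable(allocateVQC(64, 64, 3, 3))$vqc, 6912L)
  expect_identical(
    countTrainable(allocateVQC(4, 4, 1, 1),
                   circuitSpec(2, rotations = "ry_single"))$vqc, 4L)
  expect_identical(classicParamCount(64, 1, 3, 3), 576L)
  expect_identical(classicParamCount(64, 64, 3, 3), 36864L)
  expect_identical(classicParamCount(1, 1, 1, 1), 1L)
})

test_that("only LPP adds post-processing parameters, one shared head", {
  p <- allocateVQC(64, 1, 3, 3)
  expect_identical(countTrainable(p, strategy = "sst")$postprocess, 0L)
  expect_identical(countTrainable(p, strategy = "rce")$postprocess, 0L)
  expect_identical(countTrainable(p, strategy = "lpp")$postprocess,
                   p@qubitsPerVQC + 2L)
})

test_that("quantum counts grow additively in log2 while classic doubles", {
  cs <- c(64, 128, 256)
  classic <- vapply(cs, function(c) classicParamCount(c, 1, 3, 3), integer(1))
  quantum <- vapply(cs, function(c)
    countTrainable(allocateVQC(c, 1, 3, 3))$vqc, integer(1))
  expect_identical(classic, c(576L, 1152L, 2304L))
  expect_identical(quantum, c(108L, 126L, 144L))
  expect_identical(diff(quantum), c(18L, 18L))   # n_vqcs * 2 per extra qubit
})

test_that("RCE extracts real parts within [-1, 1]", {
  expect_equal(postprocessRCE(initialSuperposition(circuitSpec(2))),
               rep(0.5, 4))
  expect_equal(postprocessRCE(complex(real = -0.6, imaginary = 0.8)), -0.6)
  expect_equal(postprocessRCE(c(0 + 0i, 1 + 0i)), c(0, 1))
  set.seed(31)
  spec <- circuitSpec(3, 2)
  y <- postprocessRCE(runCircuit(spec, runif(nAngles(spec), 0, 2 * pi)))
  expect_true(all(abs(y) <= 1))
})

test_that("SST maps probabilities into [-pi/4, pi/4]", {
  expect_equal(postprocessSST(0.5), 0)
  expect_equal(postprocessSST(1), pi / 4)
  expect_equal(postprocessSST(0), -pi / 4)
  expect_error(postprocessSST(1.2), "\\[0, 1\\]")
  expect_error(postprocessSST(-0.1), "\\[0, 1\\]")
})

test_that("LPP projects probability plus binary index encoding", {
  p <- c(0.1, 0.2, 0.3, 0.15, 0.05, 0.1, 0.05, 0.05)
  # zero weights: constant bias
  expect_equal(postprocessLPP(p, list(w = numeric(4), b = 0.3)),
               rep(0.3, 8))
  # identity on the probability slot
  expect_equal(postprocessLPP(p, list(w = c(1, 0, 0, 0), b = 0)), p)
  # index 5 with 3 bits encodes as (d0, d1, d2) = (1, 0, 1)
  expect_equal(indexBits(8, 3)[6, ], c(1, 0, 1))
  # bit weights pick out the encoding
  y <- postprocessLPP(p, list(w = c(0, 1, 10, 100), b = 0))
  expect_equal(y[6], 101)
  expect_error(postprocessLPP(p, list(w = c(1, 0), b = 0)), "length")
})

test_that("kernel generation follows the channel-indexing convention", {
  set.seed(41)
  # cIn > cOut: W[ci, co, kh, kw] is value ci of the VQC owned by
  # (co, kh, kw)
  cfg <- qpgLayerConfig(cIn = 4, cOut = 2, kH = 2, kW = 2)
  W <- generateKernel(cfg)
  expect_identical(dim(W), c(4L, 2L, 2L, 2L))
  vals <- qpgnet:::.qpgOutputs(cfg)$values
  # VQC columns are ordered target-channel fastest, then kh, then kw
  v <- function(co, kh, kw) co + 2 * ((kh - 1) + 2 * (kw - 1))
  expect_equal(W[4, 2, 1, 1], vals[4, v(2, 1, 1)])
  expect_equal(W[1, 2, 2, 1], vals[1, v(2, 2, 1)])
  # cIn < cOut: roles swap
  cfg2 <- qpgLayerConfig(cIn = 2, cOut = 4, kH = 2, kW = 2)
  W2 <- generateKernel(cfg2)
  vals2 <- qpgnet:::.qpgOutputs(cfg2)$values
  expect_equal(W2[1, 2, 1, 1], vals2[2, v(1, 1, 1)])
})

test_that("zero angles with SST and 1-qubit VQCs give an exactly zero kernel", {
  cfg <- qpgLayerConfig(cIn = 2, cOut = 1, kH = 3,
                        angles = matrix(0, 2, 9))
  expect_identical(max(abs(generateKernel(cfg))), 0)
})

test_that("SST kernels are bounded by pi/4 for any angles", {
  set.seed(43)
  for (trial in 1:5) {
    cfg <- qpgLayerConfig(cIn = sample(2:6, 1), cOut = sample(2:6, 1),
                          kH = sample(1:3, 1), kW = sample(1:3, 1))
    W <- generateKernel(cfg)
    expect_lte(max(abs(W)), pi / 4 + 1e-12)
  }
})

test_that("perturbing one VQC changes only its own kernel slice", {
  set.seed(47)
  cfg <- qpgLayerConfig(cIn = 6, cOut = 3, kH = 2, kW = 2)  # target: output
  W0 <- generateKernel(cfg)
  a <- angles(cfg)
  vIdx <- 5L   # (co = 2, kh = 3 -> (kh=1,kw=2) under co-fastest ordering)
  a[, vIdx] <- a[, vIdx] + 0.3
  angles(cfg) <- a
  W1 <- generateKernel(cfg)
  changed <- which(W1 != W0, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  # vIdx = co + 3 * ((kh - 1) + 2 * (kw - 1)) = 5 -> co 2, kh 2, kw 1
  expect_true(all(changed[, 2] == 2 & changed[, 3] == 2 & changed[, 4] == 1))
})

test_that("non-power-of-two channel counts use exactly the first basis states", {
  set.seed(53)
  cfg <- qpgLayerConfig(cIn = 3, cOut = 1, kH = 1)  # 3 values from 2 qubits
  W <- generateKernel(cfg)
  S <- qpgnet:::.runBatch(cfg@circuit, angles(cfg))
  p <- qpgnet:::.bornProbs(S)
  expect_equal(as.vector(W), (pi / 2) * (p[1:3, 1] - 0.5))
})

test_that("used probabilities of a channel slice sum to at most 1", {
  set.seed(59)
  cfg <- qpgLayerConfig(cIn = 5, cOut = 1, kH = 1)
  W <- generateKernel(cfg)
  # invert SST to recover the used probabilities
  pUsed <- as.vector(W) / (pi / 2) + 0.5
  expect_lte(sum(pUsed), 1 + 1e-12)
})

test_that("kernel backward matches finite differences for every strategy", {
  set.seed(61)
  for (strat in c("sst", "rce", "lpp")) {
    cfg <- qpgLayerConfig(cIn = 3, cOut = 2, kH = 2, strategy = strat)
    dW <- array(rnorm(3 * 2 * 2 * 2), c(3, 2, 2, 2))
    bk <- qpgnet:::.qpgKernelBackward(cfg, dW)
    h <- 1e-6
    a0 <- angles(cfg)
    idx <- cbind(sample(nrow(a0), 6, replace = TRUE),
                 sample(ncol(a0), 6, replace = TRUE))
    for (r in seq_len(nrow(idx))) {
      cu <- cfg; au <- angles(cu); au[idx[r, 1], idx[r, 2]] <- au[idx[r, 1], idx[r, 2]] + h
      angles(cu) <- au
      cd <- cfg; ad <- angles(cd); ad[idx[r, 1], idx[r, 2]] <- ad[idx[r, 1], idx[r, 2]] - h
      angles(cd) <- ad
      fd <- sum(dW * (generateKernel(cu) - generateKernel(cd))) / (2 * h)
      expect_equal(bk$angles[idx[r, 1], idx[r, 2]], fd, tolerance = 1e-5)
    }
  }
})

test_that("angle initialization is uniform over [0, 1)", {
  set.seed(67)
  a <- initAngles(circuitSpec(4, 2), 50)
  expect_identical(dim(a), c(16L, 50L))
  expect_true(all(a >= 0 & a < 1))
  expect_gt(min(a), 0)          # never exactly zero-initialized
  expect_equal(mean(a), 0.5, tolerance = 0.05)
})
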