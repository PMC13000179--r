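# 2-D cross-correlation (the deep-learning convolution contract: no
# kernel flip), implemented by patch extraction (im2col) and one matrix
# multiply.  Images are arrays (H, W, C, B), kernels (cIn, cOut, kH, kW).

.im2colCache <- new.env(parent = emptyenv())

# patch-index matrix for one sample: (Ho*Wo) x (cIn*kH*kW), columns
# ordered channel-fastest then kh then kw, matching the kernel flattening
.im2colIndex <- function(H, W, C, kH, kW, pad, stride) {
  key <- paste(H, W, C, kH, kW, pad, stride, sep = "_")
  hit <- .im2colCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - kH) %/% stride + 1L
  Wo <- (Wp - kW) %/% stride + 1L
  r0 <- rep(seq(1L, by = stride, length.out = Ho), times = Wo)
  c0 <- rep(seq(1L, by = stride, length.out = Wo), each = Ho)
  off <- expand.grid(ci = seq_len(C), dh = seq_len(kH), dw = seq_len(kW))
  I <- matrix(0L, Ho * Wo, nrow(off))
  for (q in seq_len(nrow(off))) {
    r <- r0 + off$dh[q] - 1L
    cc <- c0 + off$dw[q] - 1L
    I[, q] <- r + (cc - 1L) * Hp + (off$ci[q] - 1L) * Hp * Wp
  }
  res <- list(I = I, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  .im2colCache[[key]] <- res
  res
}

.padInput <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# forward cross-correlation; returns output and the cache for backward
.convForward <- function(x, W, b = NULL, stride = 1L, pad = NULL) {
  d <- dim(x)
  kd <- dim(W)
  if (d[3] != kd[1])
    stop(sprintf("channel mismatch: input has %d channels, kernel expects %d",
                 d[3], kd[1]))
  if (is.null(pad)) pad <- (kd[3] - 1L) %/% 2L
  ix <- .im2colIndex(d[1], d[2], d[3], kd[3], kd[4], pad, stride)
  xp <- .padInput(x, pad)
  P <- nrow(ix$I); Q <- ncol(ix$I); B <- d[4]
  sampleLen <- ix$Hp * ix$Wp * d[3]
  # (P*B x Q) patch matrix, sample-major rows
  Xcol <- matrix(0, P * B, Q)
  xv <- as.vector(xp)
  offs <- (seq_len(B) - 1L) * sampleLen
  rows <- seq_len(P)
  for (bidx in seq_len(B)) {
    Xcol[(bidx - 1L) * P + rows, ] <- xv[ix$I + offs[bidx]]
  }
  Wmat <- matrix(aperm(W, c(1L, 3L, 4L, 2L)), Q, kd[2])
  Y <- Xcol %*% Wmat
  if (!is.null(b)) Y <- Y + matrix(b, nrow(Y), kd[2], byrow = TRUE)
  out <- array(0, c(ix$Ho, ix$Wo, kd[2], B))
  for (bidx in seq_len(B))
    out[, , , bidx] <- Y[(bidx - 1L) * P + rows, ]
  list(out = out,
       cache = list(Xcol = Xcol, ix = ix, dims = d, kd = kd,
                    pad = pad, stride = stride))
}

# backward: dOut (Ho, Wo, Cout, B) -> gradients on x, W, b
.convBackward <- function(cache, W, dOut, needX = TRUE) {
  d <- cache$dims; kd <- cache$kd; ix <- cache$ix
  P <- nrow(ix$I); Q <- ncol(ix$I); B <- d[4]
  dY <- matrix(0, P * B, kd[2])
  rows <- seq_len(P)
  for (bidx in seq_len(B))
    dY[(bidx - 1L) * P + rows, ] <- matrix(dOut[, , , bidx], P, kd[2])
  Wmat <- matrix(aperm(W, c(1L, 3L, 4L, 2L)), Q, kd[2])
  dWmat <- crossprod(cache$Xcol, dY)
  dW <- aperm(array(dWmat, c(kd[1], kd[3], kd[4], kd[2])), c(1L, 4L, 2L, 3L))
  db <- colSums(dY)
  dX <- NULL
  if (needX) {
    dXcol <- tcrossprod(dY, Wmat)
    sampleLen <- ix$Hp * ix$Wp * d[3]
    dxp <- numeric(sampleLen * B)
    offs <- (seq_len(B) - 1L) * sampleLen
    for (q in seq_len(Q)) {
      tgt <- rep.int(ix$I[, q], B) + rep(offs, each = P)
      dxp[tgt] <- dxp[tgt] + dXcol[, q]
    }
    dxp <- array(dxp, c(ix$Hp, ix$Wp, d[3], B))
    pad <- cache$pad
    dX <- dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- pooling / resampling / activations -------------------------------

.maxPool2 <- function(x) {
  d <- dim(x)
  o <- seq(1L, d[1], 2L); e <- o + 1L
  oc <- seq(1L, d[2], 2L); ec <- oc + 1L
  a1 <- x[o, oc, , , drop = FALSE]; a2 <- x[e, oc, , , drop = FALSE]
  a3 <- x[o, ec, , , drop = FALSE]; a4 <- x[e, ec, , , drop = FALSE]
  out <- pmax(a1, a2, a3, a4)
  list(out = out, cache = list(a = list(a1, a2, a3, a4), out = out, d = d))
}

.maxPool2Backward <- function(cache, dOut) {
  d <- cache$d
  dX <- array(0, d)
  o <- seq(1L, d[1], 2L); e <- o + 1L
  oc <- seq(1L, d[2], 2L); ec <- oc + 1L
  taken <- array(FALSE, dim(cache$out))
  sel <- list(list(o, oc), list(e, oc), list(o, ec), list(e, ec))
  for (k in 1:4) {
    m <- (cache$a[[k]] == cache$out) & !taken
    taken <- taken | m
    dX[sel[[k]][[1]], sel[[k]][[2]], , ] <- dOut * m
  }
  dX
}

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

.upsample2Backward <- function(dOut) {
  d <- dim(dOut)
  o <- seq(1L, d[1], 2L); e <- o + 1L
  oc <- seq(1L, d[2], 2L); ec <- oc + 1L
  dOut[o, oc, , , drop = FALSE] + dOut[e, oc, , , drop = FALSE] +
    dOut[o, ec, , , drop = FALSE] + dOut[e, ec, , , drop = FALSE]
}

.relu <- function(x) pmax(x, 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- per-channel batch normalization ----------------------------------
# Standard conv -> BN -> ReLU stage plumbing.  gamma/beta are trainable
# (always classically, whatever generates the conv kernel); running
# statistics are model state updated during training and used at
# evaluation time.

.bnLayer <- function(channels, momentum = 0.1, eps = 1e-5) {
  structure(list(kind = "bn",
                 gamma = rep(1, channels), beta = rep(0, channels),
                 rmean = rep(0, channels), rvar = rep(1, channels),
                 momentum = momentum, eps = eps),
            class = c("bnLayer", "qpgnetLayer"))
}

.bnForward <- function(layer, x, training = TRUE) {
  d <- dim(x)
  C <- d[3]
  if (training) {
    mu <- apply(x, 3, mean)
    v <- apply(x, 3, function(ch) mean(ch^2)) - mu^2
    rmean <- (1 - layer$momentum) * layer$rmean + layer$momentum * mu
    m <- d[1] * d[2] * d[4]
    rvar <- (1 - layer$momentum) * layer$rvar +
      layer$momentum * v * m / max(1, m - 1)
  } else {
    mu <- layer$rmean; v <- layer$rvar
    rmean <- layer$rmean; rvar <- layer$rvar
  }
  inv <- 1 / sqrt(v + layer$eps)
  bc <- function(vec) aperm(array(vec, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  xhat <- (x - bc(mu)) * bc(inv)
  out <- xhat * bc(layer$gamma) + bc(layer$beta)
  list(out = out,
       cache = list(xhat = xhat, inv = inv, d = d),
       rmean = rmean, rvar = rvar)
}

.bnBackward <- function(layer, cache, dOut) {
  d <- cache$d
  C <- d[3]
  m <- d[1] * d[2] * d[4]
  bc <- function(vec) aperm(array(vec, c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  dGamma <- apply(dOut * cache$xhat, 3, sum)
  dBeta <- apply(dOut, 3, sum)
  dXhat <- dOut * bc(layer$gamma)
  sum1 <- apply(dXhat, 3, sum)
  sum2 <- apply(dXhat * cache$xhat, 3, sum)
  dX <- bc(cache$inv) * (dXhat - bc(sum1 / m) - cache$xhat * bc(sum2 / m))
  list(dX = dX, gamma = dGamma, beta = dBeta)
}

# ---- layer constructors ------------------------------------------------

#' Create a QPG-trained convolution layer
#'
#' A convolution layer whose kernel is regenerated from its VQC bank on
#' every forward pass; the trainable set is the VQC rotation angles (plus
#' the shared LPP head when that strategy is selected).  No bias term.
#'
#' @param cIn,cOut,kH,kW layer dimensions.
#' @param strategy post-processing strategy (`"sst"`, `"rce"`, `"lpp"`).
#' @param nBlocks circuit depth K.
#' @param rotations circuit rotation layout (see [circuitSpec()]).
#' @param stride,pad convolution stride and zero padding; `pad = NULL`
#'   means "same" padding for odd kernels.
#' @param config optionally a ready-made [`QPGLayerConfig-class`]
#'   (overrides the other circuit arguments).
#' @return a layer object (list with class `"qpgConvLayer"`).
#' @examples
#' set.seed(1)
#' ly <- qpgConvLayer(2, 1, 3)
#' x <- array(rnorm(2 * 8 * 8), c(8, 8, 2, 1))
#' dim(qpgConvForward(x, ly))
#' @export
qpgConvLayer <- function(cIn, cOut, kH, kW = kH,
                         strategy = c("sst", "rce", "lpp"),
                         nBlocks = 1L,
                         rotations = c("ry_rx", "ry_only", "ry_single"),
                         stride = 1L, pad = NULL, config = NULL) {
  strategy <- match.arg(strategy)
  rotations <- match.arg(rotations)
  if (is.null(config)) {
    plan <- allocateVQC(cIn, cOut, kH, kW)
    config <- qpgLayerConfig(
      plan = plan,
      circuit = circuitSpec(plan@qubitsPerVQC, nBlocks, rotations = rotations),
      strategy = strategy)
  }
  structure(list(kind = "qpgconv", config = config,
                 stride = as.integer(stride), pad = pad),
            class = c("qpgConvLayer", "qpgnetLayer"))
}

#' Create a QPG-adaptation convolution layer
#'
#' Keeps a frozen base kernel (e.g. pre-trained weights) and adds a
#' quantum-generated increment: the effective kernel is
#' `base + generateKernel(config)`.  Only the VQC angles (and LPP head)
#' are trainable; the base never receives gradient.
#'
#' @param base frozen 4-D base kernel `(cIn, cOut, kH, kW)`.
#' @inheritParams qpgConvLayer
#' @return a layer object (list with class `"qpgaConvLayer"`).
#' @export
qpgaConvLayer <- function(base, strategy = c("sst", "rce", "lpp"),
                          nBlocks = 1L,
                          rotations = c("ry_rx", "ry_only", "ry_single"),
                          stride = 1L, pad = NULL, config = NULL) {
  strategy <- match.arg(strategy)
  rotations <- match.arg(rotations)
  d <- dim(base)
  if (length(d) != 4L) stop("base kernel must be a 4-D array")
  if (is.null(config)) {
    plan <- allocateVQC(d[1], d[2], d[3], d[4])
    config <- qpgLayerConfig(
      plan = plan,
      circuit = circuitSpec(plan@qubitsPerVQC, nBlocks, rotations = rotations),
      strategy = strategy)
  }
  pd <- config@plan
  if (!identical(d, c(pd@cIn, pd@cOut, pd@kH, pd@kW)))
    stop("base kernel shape does not match the layer configuration")
  structure(list(kind = "qpgaconv", base = base, config = config,
                 stride = as.integer(stride), pad = pad),
            class = c("qpgaConvLayer", "qpgnetLayer"))
}

#' Create a low-rank adaptation (ConvLoRA) convolution layer
#'
#' Baseline adapter: the frozen base kernel receives an additive low-rank
#' update factorized per kernel position — at each `(kh, kw)` the
#' `cOut x cIn` slice increment is `B[,,pos] %*% A[,,pos]` with
#' `A: r x cIn` and `B: cOut x r`.  Trainable count is
#' `r * (cIn + cOut) * kH * kW`.  `B` starts at zero so training begins
#' from the base kernel.
#'
#' @param base frozen 4-D base kernel `(cIn, cOut, kH, kW)`.
#' @param rank adaptation rank r (>= 1).
#' @param stride,pad convolution geometry.
#' @return a layer object (list with class `"convLoRALayer"`).
#' @export
convLoRALayer <- function(base, rank, stride = 1L, pad = NULL) {
  d <- dim(base)
  if (length(d) != 4L) stop("base kernel must be a 4-D array")
  if (rank < 1L) stop("rank must be >= 1")
  npos <- d[3] * d[4]
  A <- array(stats::rnorm(rank * d[1] * npos, sd = 1 / sqrt(d[1])),
             c(rank, d[1], npos))
  B <- array(0, c(d[2], rank, npos))
  structure(list(kind = "convlora", base = base, A = A, B = B,
                 rank = as.integer(rank),
                 stride = as.integer(stride), pad = pad),
            class = c("convLoRALayer", "qpgnetLayer"))
}

#' Create a classical convolution layer
#'
#' Standard trainable convolution with Kaiming (fan-in variance-scaling)
#' weight initialization and zero bias.
#'
#' @param cIn,cOut,kH,kW layer dimensions.
#' @param stride,pad convolution geometry.
#' @param bias include a bias term (default `TRUE`).
#' @return a layer object (list with class `"convLayer"`).
#' @export
convLayer <- function(cIn, cOut, kH, kW = kH, stride = 1L, pad = NULL,
                      bias = TRUE) {
  fanIn <- cIn * kH * kW
  W <- array(stats::rnorm(cIn * cOut * kH * kW, sd = sqrt(2 / fanIn)),
             c(cIn, cOut, kH, kW))
  structure(list(kind = "conv", W = W,
                 b = if (bias) numeric(cOut) else NULL,
                 stride = as.integer(stride), pad = pad),
            class = c("convLayer", "qpgnetLayer"))
}

#' Effective kernel of any qpgnet layer
#'
#' Materializes the 4-D kernel a layer would convolve with right now:
#' the stored weights for a classical layer, the freshly generated
#' quantum kernel for QPGConv, base plus quantum increment for QPGAConv,
#' and base plus low-rank update for ConvLoRA.
#'
#' @param layer a layer object.
#' @return numeric 4-D array `(cIn, cOut, kH, kW)`.
#' @export
layerKernel <- function(layer) {
  switch(layer$kind,
    conv = layer$W,
    qpgconv = generateKernel(layer$config),
    qpgaconv = layer$base + generateKernel(layer$config),
    convlora = layer$base + .loraDelta(layer),
    stop("unknown layer kind"))
}

.loraDelta <- function(layer) {
  d <- dim(layer$base)
  delta <- array(0, d)
  pos <- 0L
  for (kw in seq_len(d[4])) for (kh in seq_len(d[3])) {
    pos <- pos + 1L
    delta[, , kh, kw] <- t(layer$B[, , pos, drop = FALSE][, , 1] %*%
                             layer$A[, , pos, drop = FALSE][, , 1])
  }
  delta
}

#' Forward pass of a QPG convolution layer
#'
#' Regenerates the kernel from the layer's VQCs and convolves the input
#' batch with it (cross-correlation, default stride 1 and "same"
#' padding).  No bias is added.
#'
#' @param x input array `(H, W, cIn, batch)`.
#' @param layer a layer from [qpgConvLayer()].
#' @return output array `(H', W', cOut, batch)`.
#' @export
qpgConvForward <- function(x, layer) {
  .convForward(x, layerKernel(layer), NULL, layer$stride, layer$pad)$out
}

#' Forward pass of a QPG-adaptation convolution layer
#'
#' Convolves with the frozen base kernel plus the quantum-generated
#' increment.
#'
#' @param x input array `(H, W, cIn, batch)`.
#' @param layer a layer from [qpgaConvLayer()].
#' @return output array `(H', W', cOut, batch)`.
#' @export
qpgaConvForward <- function(x, layer) {
  .convForward(x, layerKernel(layer), NULL, layer$stride, layer$pad)$out
}

#' Trainable-parameter count of the ConvLoRA baseline
#'
#' @param cIn,cOut,kH,kW layer dimensions.
#' @param rank adaptation rank r.
#' @return integer `rank * (cIn + cOut) * kH * kW`.
#' @examples
#' convLoRAParamCount(64, 64, 3, 3, rank = 8)  # 9216
#' @export
convLoRAParamCount <- function(cIn, cOut, kH, kW = kH, rank) {
  if (rank < 1L) stop("rank must be >= 1")
  as.integer(rank * (cIn + cOut) * kH * kW)
}

# trainable parameter tensors of a layer, as a named list
.layerParams <- function(layer) {
  switch(layer$kind,
    bn = list(gamma = layer$gamma, beta = layer$beta),
    conv = {
      p <- list(W = layer$W)
      if (!is.null(layer$b)) p$b <- layer$b
      p
    },
    qpgconv = ,
    qpgaconv = {
      p <- list(angles = layer$config@angles)
      if (identical(layer$config@strategy, "lpp")) {
        p$headW <- layer$config@head$w
        p$headB <- layer$config@head$b
      }
      p
    },
    convlora = list(A = layer$A, B = layer$B))
}

.setLayerParams <- function(layer, p) {
  switch(layer$kind,
    bn = {
      layer$gamma <- p$gamma
      layer$beta <- p$beta
    },
    conv = {
      layer$W <- p$W
      if (!is.null(layer$b)) layer$b <- p$b
    },
    qpgconv = ,
    qpgaconv = {
      layer$config@angles <- p$angles
      if (identical(layer$config@strategy, "lpp"))
        layer$config@head <- list(w = p$headW, b = p$headB)
    },
    convlora = {
      layer$A <- p$A
      layer$B <- p$B
    })
  layer
}

# gradient of the loss w.r.t. a layer's trainable parameters, given
# dL/dW on the effective kernel (and dL/db where a bias exists)
.layerParamGrads <- function(layer, dW, db = NULL) {
  switch(layer$kind,
    conv = {
      g <- list(W = dW)
      if (!is.null(layer$b)) g$b <- db
      g
    },
    qpgconv = ,
    qpgaconv = {
      bk <- .qpgKernelBackward(layer$config, dW)
      g <- list(angles = bk$angles)
      if (identical(layer$config@strategy, "lpp")) {
        g$headW <- bk$head$w
        g$headB <- bk$head$b
      }
      g
    },
    convlora = {
      d <- dim(layer$base)
      dA <- array(0, dim(layer$A))
      dB <- array(0, dim(layer$B))
      pos <- 0L
      for (kw in seq_len(d[4])) for (kh in seq_len(d[3])) {
        pos <- pos + 1L
        dDelta <- t(dW[, , kh, kw])   # cOut x cIn
        dB[, , pos] <- dDelta %*% t(layer$A[, , pos, drop = FALSE][, , 1])
        dA[, , pos] <- t(layer$B[, , pos, drop = FALSE][, , 1]) %*% dDelta
      }
      list(A = dA, B = dB)
    })
}
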