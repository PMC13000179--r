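# The eleven integration schemes: which named components of the
# encoder-decoder are trained through quantum parameter generation.
.schemeTable <- list(
  `1` = c("encoder1", "finalconv"),
  `2` = c("encoder1", "block2", "finalconv"),
  `3` = c("encoder1", "block2", "dblock2"),
  `4` = c("block1", "block2"),
  `5` = c("block1", "block2", "dblock1"),
  `6` = c("block1", "block2", "dblock2"),
  `7` = c("block1", "block2", "dblock1", "dblock2"),
  `8` = c("block1", "block2", "dblock1", "dblock2", "finalconv"),
  `9` = c("block2", "finalconv"),
  `10` = c("block2", "dblock2", "finalconv"),
  `11` = c("block2", "dblock1", "dblock2", "finalconv")
)

.componentNames <- c("encoder1", "block1", "block2",
                     "dblock1", "dblock2", "finalconv")

#' Components switched to quantum training under a scheme
#'
#' @param scheme integer scheme id in 1..11, or 0 for the fully classical
#'   model.
#' @return character vector of component names.
#' @examples
#' schemeComponents(3)  # encoder1, block2, dblock2
#' @export
schemeComponents <- function(scheme) {
  if (length(scheme) != 1L || is.na(scheme) || scheme != round(scheme) ||
      scheme < 0 || scheme > 11)
    stop("scheme must be a single integer in 0..11")
  if (scheme == 0) character(0) else .schemeTable[[as.character(scheme)]]
}

#' Build a miniature hybrid segmentation model
#'
#' Constructs a small UNext-style encoder-decoder for binary
#' segmentation: three 3x3 convolution stages on the way down
#' (`encoder1`, `block1`, `block2`, with 2x max-pooling after the first
#' two), two 3x3 stages on the way up (`dblock1`, `dblock2`, each after
#' 2x nearest-neighbour upsampling, with additive skip connections from
#' the matching encoder stage), and a 1x1 sigmoid head (`finalconv`).
#' Each named component is trained either classically or through quantum
#' parameter generation, as dictated by the scheme.
#'
#' The default stage widths (8, 16, 32) make every QPG-able site exercise
#' both branches of the channel-allocation rule: channel-up convolutions
#' on the encoder side, channel-down on the decoder side.
#'
#' @param scheme integer scheme id (0 = fully classical) or a character
#'   vector of component names.
#' @param inputSize side length of the square input images (a multiple of
#'   4; default 32).
#' @param widths integer vector of the three encoder stage widths.
#' @param strategy post-processing strategy for the QPG layers.
#' @param nBlocks circuit depth K of each VQC.
#' @param rotations circuit rotation layout.
#' @return a [`HybridSegModel-class`].
#' @examples
#' set.seed(1)
#' m <- buildSegModel(scheme = 3)
#' parameterReport(m)
#' @export
buildSegModel <- function(scheme = 0, inputSize = 32L,
                          widths = c(8L, 16L, 32L),
                          strategy = c("sst", "rce", "lpp"),
                          nBlocks = 1L,
                          rotations = c("ry_rx", "ry_only", "ry_single")) {
  strategy <- match.arg(strategy)
  rotations <- match.arg(rotations)
  if (is.character(scheme)) {
    comps <- scheme
    schemeId <- -1L
  } else {
    comps <- schemeComponents(scheme)
    schemeId <- as.integer(scheme)
  }
  if (!all(comps %in% .componentNames))
    stop("unknown component(s): ",
         paste(setdiff(comps, .componentNames), collapse = ", "))
  if (inputSize %% 4L != 0L || inputSize < 8L)
    stop("inputSize must be a multiple of 4, at least 8")
  w <- as.integer(widths)
  dims <- list(
    encoder1 = c(1L, w[1], 3L, 3L),
    block1 = c(w[1], w[2], 3L, 3L),
    block2 = c(w[2], w[3], 3L, 3L),
    dblock1 = c(w[3], w[2], 3L, 3L),
    dblock2 = c(w[2], w[1], 3L, 3L),
    finalconv = c(w[1], 1L, 1L, 1L)
  )
  layers <- lapply(.componentNames, function(nm) {
    d <- dims[[nm]]
    if (nm %in% comps)
      qpgConvLayer(d[1], d[2], d[3], d[4], strategy = strategy,
                   nBlocks = nBlocks, rotations = rotations)
    else
      convLayer(d[1], d[2], d[3], d[4])
  })
  names(layers) <- .componentNames
  # every conv stage except the 1x1 head is followed by per-channel batch
  # normalization (conv -> BN -> ReLU), trained classically throughout
  for (nm in setdiff(.componentNames, "finalconv"))
    layers[[paste0(nm, "_bn")]] <- .bnLayer(dims[[nm]][2])
  new("HybridSegModel", layers = layers, components = comps,
      scheme = schemeId, strategy = strategy,
      inputSize = as.integer(inputSize), widths = w)
}

#' Per-component trainable-parameter report
#'
#' Itemizes, for every named component, the classically trained parameter
#' count and the quantum (VQC angle + post-processing) count.
#'
#' @param model a [`HybridSegModel-class`].
#' @return a data.frame with columns `component`, `kind`, `classical`,
#'   `quantum`.
#' @export
parameterReport <- function(model) {
  rows <- lapply(.componentNames, function(nm) {
    ly <- model@layers[[nm]]
    bn <- model@layers[[paste0(nm, "_bn")]]
    bnParams <- if (is.null(bn)) 0L else length(bn$gamma) + length(bn$beta)
    if (ly$kind == "conv") {
      n <- length(ly$W) + length(ly$b) + bnParams
      data.frame(component = nm, kind = "classical",
                 classical = as.integer(n), quantum = 0L)
    } else {
      ct <- countTrainable(ly$config@plan, ly$config@circuit,
                           ly$config@strategy)
      data.frame(component = nm, kind = toupper(ly$kind),
                 classical = as.integer(bnParams), quantum = ct$total)
    }
  })
  do.call(rbind, rows)
}

# full forward pass; keepCache retains every intermediate needed by the
# backward pass (conv caches, pre-activations, pooling argmaxes).
# training = TRUE uses batch statistics in the BN stages (and reports
# updated running statistics); FALSE uses the stored running statistics.
.segForwardFull <- function(model, x, keepCache = FALSE, training = keepCache) {
  ly <- model@layers
  convNames <- .componentNames
  kernels <- lapply(convNames, function(nm) layerKernel(ly[[nm]]))
  names(kernels) <- convNames
  cv <- function(nm, input) {
    .convForward(input, kernels[[nm]], ly[[nm]]$b, ly[[nm]]$stride,
                 ly[[nm]]$pad)
  }
  bn <- function(nm, f) .bnForward(ly[[paste0(nm, "_bn")]], f$out, training)
  f1 <- cv("encoder1", x);      n1 <- bn("encoder1", f1)
  e1 <- .relu(n1$out)
  p1 <- .maxPool2(e1)
  f2 <- cv("block1", p1$out);   n2 <- bn("block1", f2)
  b1 <- .relu(n2$out)
  p2 <- .maxPool2(b1)
  f3 <- cv("block2", p2$out);   n3 <- bn("block2", f3)
  b2 <- .relu(n3$out)
  u1 <- .upsample2(b2)
  f4 <- cv("dblock1", u1);      n4 <- bn("dblock1", f4)
  z4 <- n4$out + b1;            d1 <- .relu(z4)
  u2 <- .upsample2(d1)
  f5 <- cv("dblock2", u2);      n5 <- bn("dblock2", f5)
  z5 <- n5$out + e1;            d2 <- .relu(z5)
  f6 <- cv("finalconv", d2)
  logits <- f6$out
  prob <- .sigmoid(logits)
  bnState <- list(encoder1 = n1, block1 = n2, block2 = n3,
                  dblock1 = n4, dblock2 = n5)
  if (!keepCache) return(list(prob = prob, logits = logits))
  list(prob = prob, logits = logits, kernels = kernels,
       bnState = bnState,
       cache = list(f1 = f1, n1 = n1, e1 = e1, p1 = p1,
                    f2 = f2, n2 = n2, b1 = b1, p2 = p2,
                    f3 = f3, n3 = n3, b2 = b2,
                    f4 = f4, n4 = n4, z4 = z4, d1 = d1,
                    f5 = f5, n5 = n5, z5 = z5, d2 = d2, f6 = f6))
}

#' Forward pass of a hybrid segmentation model
#'
#' Uses the stored batch-normalization running statistics (inference
#' mode).
#'
#' @param model a [`HybridSegModel-class`].
#' @param x input array `(H, W, 1, batch)` or a single `(H, W)` matrix.
#' @return array `(H, W, 1, batch)` of mask probabilities in (0, 1).
#' @export
segForward <- function(model, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  d <- dim(x)
  if (d[1] != model@inputSize || d[2] != model@inputSize || d[3] != 1L)
    stop(sprintf("input must be (%d, %d, 1, batch)",
                 model@inputSize, model@inputSize))
  .segForwardFull(model, x, keepCache = FALSE, training = FALSE)$prob
}

# backward pass: dL/dlogits -> per-component parameter gradients
.segBackward <- function(model, fw, dLogits) {
  ly <- model@layers
  K <- fw$kernels
  ch <- fw$cache
  grads <- list()
  reluBack <- function(d, z) d * (z > 0)
  bnBack <- function(nm, n, dOut) {
    bb <- .bnBackward(ly[[paste0(nm, "_bn")]], n$cache, dOut)
    grads[[paste0(nm, "_bn")]] <<- list(gamma = bb$gamma, beta = bb$beta)
    bb$dX
  }

  g6 <- .convBackward(ch$f6$cache, K$finalconv, dLogits)
  grads$finalconv <- .layerParamGrads(ly$finalconv, g6$dW, g6$db)
  dz5 <- reluBack(g6$dX, ch$z5)
  de1FromSkip <- dz5                        # skip add into z5
  g5 <- .convBackward(ch$f5$cache, K$dblock2, bnBack("dblock2", ch$n5, dz5))
  grads$dblock2 <- .layerParamGrads(ly$dblock2, g5$dW, g5$db)
  dz4 <- reluBack(.upsample2Backward(g5$dX), ch$z4)
  db1FromSkip <- dz4                        # skip add into z4
  g4 <- .convBackward(ch$f4$cache, K$dblock1, bnBack("dblock1", ch$n4, dz4))
  grads$dblock1 <- .layerParamGrads(ly$dblock1, g4$dW, g4$db)
  db2 <- reluBack(.upsample2Backward(g4$dX), ch$n3$out)
  g3 <- .convBackward(ch$f3$cache, K$block2, bnBack("block2", ch$n3, db2))
  grads$block2 <- .layerParamGrads(ly$block2, g3$dW, g3$db)
  db1 <- .maxPool2Backward(ch$p2$cache, g3$dX) + db1FromSkip
  db1 <- reluBack(db1, ch$n2$out)
  g2 <- .convBackward(ch$f2$cache, K$block1, bnBack("block1", ch$n2, db1))
  grads$block1 <- .layerParamGrads(ly$block1, g2$dW, g2$db)
  de1 <- .maxPool2Backward(ch$p1$cache, g2$dX) + de1FromSkip
  de1 <- reluBack(de1, ch$n1$out)
  g1 <- .convBackward(ch$f1$cache, K$encoder1, bnBack("encoder1", ch$n1, de1),
                      needX = FALSE)
  grads$encoder1 <- .layerParamGrads(ly$encoder1, g1$dW, g1$db)
  grads
}
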