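#' Training configuration
#'
#' Optimizer and loop settings for hybrid training: Adam with learning
#' rate 0.001 and weight decay 5e-4, batch size 8, 20 epochs, no
#' learning-rate scheduler.  The loss defaults to binary cross-entropy
#' plus soft Dice, a standard pairing for binary medical segmentation.
#'
#' @param lr learning rate.
#' @param weightDecay L2 weight decay added to every gradient.
#' @param batchSize minibatch size.
#' @param epochs number of epochs.
#' @param seed RNG seed; a fixed seed makes the run bitwise reproducible.
#' @param loss `"bce_dice"` (default), `"bce"`, or `"dice"`.
#' @param threshold binarization threshold for evaluation.
#' @param freezeQuantum keep all VQC angles (and LPP heads) fixed; QPG
#'   kernels then stay constant across steps while classical parameters
#'   train normally.
#' @return list of settings (class `"trainConfig"`).
#' @export
trainConfig <- function(lr = 0.001, weightDecay = 5e-4, batchSize = 8L,
                        epochs = 20L, seed = 1L,
                        loss = c("bce_dice", "bce", "dice"),
                        threshold = 0.5, freezeQuantum = FALSE) {
  loss <- match.arg(loss)
  stopifnot(lr > 0, weightDecay >= 0, batchSize >= 1, epochs >= 1)
  structure(list(lr = lr, weightDecay = weightDecay,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss = loss, threshold = threshold,
                 freezeQuantum = isTRUE(freezeQuantum)),
            class = "trainConfig")
}

# loss value and gradient w.r.t. the logits.  prob = sigmoid(logits);
# BCE grad through the sigmoid is (p - t) / npix; soft Dice is computed
# per sample and averaged.
.segLoss <- function(prob, logits, target, kind) {
  eps <- 1e-7
  d <- dim(prob)
  B <- d[4]
  npix <- prod(d[1:3])
  p <- pmin(pmax(prob, eps), 1 - eps)
  loss <- 0
  dLogits <- array(0, d)
  if (kind %in% c("bce", "bce_dice")) {
    loss <- loss - mean(target * log(p) + (1 - target) * log(1 - p))
    dLogits <- dLogits + (prob - target) / (npix * B)
  }
  if (kind %in% c("dice", "bce_dice")) {
    sm <- 1
    for (k in seq_len(B)) {
      pk <- prob[, , , k]; tk <- target[, , , k]
      inter <- sum(pk * tk); tot <- sum(pk) + sum(tk)
      dice <- (2 * inter + sm) / (tot + sm)
      loss <- loss + (1 - dice) / B
      dDice <- (2 * tk * (tot + sm) - (2 * inter + sm)) / (tot + sm)^2
      dLogits[, , , k] <- dLogits[, , , k] -
        dDice * pk * (1 - pk) / B
    }
  }
  list(loss = loss, dLogits = dLogits)
}

# Adam with decoupled-from-nothing classic L2: grad <- grad + wd * param
.adamInit <- function(params) {
  lapply(params, function(p) lapply(p, function(v)
    list(m = array(0, dim(v) %||% length(v)), v = array(0, dim(v) %||% length(v)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamStep <- function(params, grads, state, t, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      frozen = character(0)) {
  quantumNames <- c("angles", "headW", "headB")
  for (nm in names(params)) {
    for (pn in names(params[[nm]])) {
      if (length(frozen) && pn %in% quantumNames && "quantum" %in% frozen)
        next
      g <- grads[[nm]][[pn]] + wd * params[[nm]][[pn]]
      st <- state[[nm]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      params[[nm]][[pn]] <- params[[nm]][[pn]] - lr * mh / (sqrt(vh) + eps)
      state[[nm]][[pn]] <- st
    }
  }
  list(params = params, state = state)
}

.modelParams <- function(model) lapply(model@layers, .layerParams)

.setModelParams <- function(model, params) {
  for (nm in names(params))
    model@layers[[nm]] <- .setLayerParams(model@layers[[nm]], params[[nm]])
  model
}

#' Train a hybrid segmentation model
#'
#' The hybrid loop: every forward pass regenerates the kernels of the
#' QPG layers from their current angles, the loss gradient is
#' backpropagated through the convolutions and (analytically) through the
#' circuit simulator to the rotation angles, and a single Adam step
#' updates quantum and classical parameters together.  After each epoch
#' the model is evaluated on the test set; the best epoch's test metrics
#' are retained.
#'
#' @param model a [`HybridSegModel-class`] (freshly built models carry
#'   uniform \[0, 1) angles and Kaiming classical weights).
#' @param train,test lists with arrays `x` and `y` of dim
#'   `(H, W, 1, n)` (see [stackSamples()]); `test = NULL` skips
#'   evaluation.
#' @param config a [trainConfig()].
#' @param verbose print one line per epoch.
#' @return list with components `model` (trained), `history` (data.frame
#'   of epoch, meanLoss, testIoU, testDSC), `best` (list with `epoch`,
#'   `iou`, `dsc`), and `stepLoss` (numeric vector of per-step losses).
#' @export
trainModel <- function(model, train, test = NULL, config = trainConfig(),
                       verbose = FALSE) {
  nTrain <- dim(train$x)[4]
  if (is.null(nTrain) || nTrain < 1L) stop("training dataset is empty")
  set.seed(config$seed)
  params <- .modelParams(model)
  state <- .adamInit(params)
  t <- 0L
  stepLoss <- numeric(0)
  hist <- data.frame(epoch = integer(0), meanLoss = numeric(0),
                     testIoU = numeric(0), testDSC = numeric(0))
  best <- list(epoch = NA_integer_, iou = -Inf, dsc = -Inf)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nTrain)
    lossAcc <- numeric(0)
    for (start in seq(1L, nTrain, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, nTrain)]
      xb <- train$x[, , , idx, drop = FALSE]
      yb <- train$y[, , , idx, drop = FALSE]
      model <- .setModelParams(model, params)
      fw <- .segForwardFull(model, xb, keepCache = TRUE)
      for (nm in names(fw$bnState)) {   # BN running statistics are state
        bnm <- paste0(nm, "_bn")
        model@layers[[bnm]]$rmean <- fw$bnState[[nm]]$rmean
        model@layers[[bnm]]$rvar <- fw$bnState[[nm]]$rvar
      }
      ls <- .segLoss(fw$prob, fw$logits, yb, config$loss)
      if (!is.finite(ls$loss))
        stop(sprintf("non-finite loss (%g) at epoch %d; aborting", ls$loss, ep))
      grads <- .segBackward(model, fw, ls$dLogits)
      t <- t + 1L
      upd <- .adamStep(params, grads, state, t, config$lr, config$weightDecay,
                       frozen = if (config$freezeQuantum) "quantum"
                                else character(0))
      params <- upd$params
      state <- upd$state
      lossAcc <- c(lossAcc, ls$loss)
    }
    stepLoss <- c(stepLoss, lossAcc)
    model <- .setModelParams(model, params)
    tIoU <- NA_real_; tDSC <- NA_real_
    if (!is.null(test)) {
      rep <- evaluateModel(model, test, threshold = config$threshold)
      s <- metricsSummary(rep)
      tIoU <- s$meanIoU; tDSC <- s$meanDSC
      if (tDSC > best$dsc)
        best <- list(epoch = ep, iou = tIoU, dsc = tDSC)
    }
    hist <- rbind(hist, data.frame(epoch = ep, meanLoss = mean(lossAcc),
                                   testIoU = tIoU, testDSC = tDSC))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, test IoU %.4f, test DSC %.4f",
                      ep, mean(lossAcc), tIoU, tDSC))
  }
  list(model = model, history = hist, best = best, stepLoss = stepLoss)
}

#' Fit a QPG layer's angles to a target kernel
#'
#' Parameter-recovery optimization: trains the VQC angles (and LPP head,
#' if any) of a single QPG convolution layer so that its generated kernel
#' matches `target` under mean squared error, using Adam.
#'
#' @param config a [`QPGLayerConfig-class`] providing the starting
#'   angles.
#' @param target numeric 4-D target kernel `(cIn, cOut, kH, kW)`.
#' @param steps number of Adam steps.
#' @param lr learning rate.
#' @return list with `config` (fitted), `maxError` (final max absolute
#'   kernel deviation), and `mseTrace` (per-step MSE).
#' @export
fitQPGKernel <- function(config, target, steps = 500L, lr = 0.05) {
  pl <- config@plan
  if (!identical(dim(target),
                 as.integer(c(pl@cIn, pl@cOut, pl@kH, pl@kW))))
    stop("target kernel shape does not match the layer configuration")
  layer <- structure(list(kind = "qpgconv", config = config),
                     class = c("qpgConvLayer", "qpgnetLayer"))
  params <- list(layer = .layerParams(layer))
  state <- .adamInit(params)
  mse <- numeric(steps)
  for (t in seq_len(steps)) {
    layer <- .setLayerParams(layer, params$layer)
    W <- generateKernel(layer$config)
    diff <- W - target
    mse[t] <- mean(diff^2)
    dW <- 2 * diff / length(diff)
    grads <- list(layer = .layerParamGrads(layer, dW))
    upd <- .adamStep(params, grads, state, t, lr, 0)
    params <- upd$params
    state <- upd$state
  }
  layer <- .setLayerParams(layer, params$layer)
  W <- generateKernel(layer$config)
  list(config = layer$config, maxError = max(abs(W - target)),
       mseTrace = mse)
}
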