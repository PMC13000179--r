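#' Allocate variational circuits across a convolution kernel
#'
#' Implements the channel-indexing rule of quantum parameter generation:
#' the smaller channel axis becomes the target axis (ties go to the input
#' axis), one VQC is allocated per target channel and kernel position, and
#' each VQC emits one weight per channel of the larger axis, so it needs
#' `ceiling(log2(max(cIn, cOut)))` qubits (at least 1).
#'
#' @param cIn,cOut input/output channel counts (>= 1).
#' @param kH,kW kernel height and width (>= 1).
#' @return an [`AllocationPlan-class`].
#' @examples
#' allocateVQC(512, 32, 2, 2)  # 128 nine-qubit VQCs, target axis "output"
#' allocateVQC(64, 256, 3, 3)  # 576 eight-qubit VQCs, target axis "input"
#' @export
allocateVQC <- function(cIn, cOut, kH, kW = kH) {
  dims <- c(cIn, cOut, kH, kW)
  if (any(!is.finite(dims)) || any(dims < 1) || any(dims != round(dims)))
    stop("cIn, cOut, kH, kW must all be integers >= 1")
  cIn <- as.integer(cIn); cOut <- as.integer(cOut)
  kH <- as.integer(kH); kW <- as.integer(kW)
  values <- max(cIn, cOut)
  new("AllocationPlan",
      cIn = cIn, cOut = cOut, kH = kH, kW = kW,
      targetAxis = if (cIn <= cOut) "input" else "output",
      nVQCs = min(cIn, cOut) * kH * kW,
      qubitsPerVQC = max(1L, as.integer(ceiling(log2(values)))),
      valuesPerVQC = as.integer(values))
}

#' Trainable-parameter ledger of a QPG layer
#'
#' Counts the rotation angles across all VQCs of a layer, and separately
#' the parameters added by the post-processing strategy (only `"lpp"` adds
#' any: one shared linear head of `qubitsPerVQC + 2` values).  The
#' headline quantum count of a layer is the `vqc` entry; `"sst"` and
#' `"rce"` add nothing.
#'
#' @param plan an [`AllocationPlan-class`].
#' @param circuit a [`CircuitSpec-class`]; its `nQubits` must match the
#'   plan's `qubitsPerVQC`.
#' @param strategy `"sst"` (default), `"rce"`, or `"lpp"`.
#' @return list with integer components `vqc`, `postprocess`, `total`.
#' @examples
#' countTrainable(allocateVQC(64, 1, 3, 3), circuitSpec(6))$vqc   # 108
#' countTrainable(allocateVQC(64, 64, 3, 3), circuitSpec(6))$vqc  # 6912
#' @export
countTrainable <- function(plan, circuit = circuitSpec(plan@qubitsPerVQC),
                           strategy = c("sst", "rce", "lpp")) {
  strategy <- match.arg(strategy)
  if (circuit@nQubits != plan@qubitsPerVQC)
    stop("circuit nQubits must equal the plan's qubitsPerVQC")
  vqc <- plan@nVQCs * nAngles(circuit)
  post <- if (strategy == "lpp") plan@qubitsPerVQC + 2L else 0L
  list(vqc = as.integer(vqc), postprocess = as.integer(post),
       total = as.integer(vqc + post))
}

#' Classical trainable-parameter count of a convolution kernel
#'
#' @param cIn,cOut,kH,kW layer dimensions.
#' @return integer `cIn * cOut * kH * kW` (bias-free accounting).
#' @examples
#' classicParamCount(64, 1, 3, 3)  # 576
#' @export
classicParamCount <- function(cIn, cOut, kH, kW = kH) {
  as.integer(cIn * cOut * kH * kW)
}

# ---- post-processing strategies ---------------------------------------

#' Real-component extraction (RCE)
#'
#' Maps a quantum state to weights by taking the real part of each
#' amplitude; values lie in \[-1, 1\].  Exact amplitude access is a
#' simulator-side capability.
#'
#' @param amplitudes complex amplitude vector of a normalized state.
#' @return numeric vector `Re(amplitudes)`.
#' @export
postprocessRCE <- function(amplitudes) Re(amplitudes)

#' Shift-and-scale transformation (SST)
#'
#' Maps measurement probabilities to `(pi/2) * (p - 0.5)`, landing in
#' \[-pi/4, pi/4\] so that negative weights are representable without any
#' extra parameters.
#'
#' @param probs numeric probabilities in \[0, 1\].
#' @return numeric vector in \[-pi/4, pi/4\].
#' @export
postprocessSST <- function(probs) {
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  (pi / 2) * (probs - 0.5)
}

#' Linear probability projection (LPP)
#'
#' Projects each probability, concatenated with the binary encoding of its
#' basis-state index, through a learned linear head:
#' `y_i = w . (p_i, d_0, ..., d_k) + b`, where `(d_k ... d_0)` is the
#' `nBits`-bit binary representation of `i` with `d_0` the least
#' significant bit.
#'
#' @param probs numeric probabilities for basis states `0 .. length-1`.
#' @param head list with `w` (length `nBits + 1`: probability slot first,
#'   then bit slots `d_0 .. d_k`) and scalar `b`.
#' @param nBits number of index bits; defaults to the smallest width
#'   covering all of `probs`.
#' @return numeric vector of projected values.
#' @export
postprocessLPP <- function(probs, head,
                           nBits = max(1L, ceiling(log2(length(probs))))) {
  if (length(head$w) != nBits + 1L || length(head$b) != 1L)
    stop(sprintf("lpp head must have w of length %d and a scalar b", nBits + 1L))
  B <- indexBits(length(probs), nBits)
  as.vector(head$w[1L] * probs + B %*% head$w[-1L] + head$b)
}

#' Binary encodings of basis-state indices
#'
#' @param n number of basis states (indices `0 .. n-1`).
#' @param nBits bit width.
#' @return an `n x nBits` 0/1 matrix; column j holds bit `d_{j-1}` (column
#'   1 is the least significant bit).
#' @export
indexBits <- function(n, nBits) {
  idx <- 0:(n - 1L)
  vapply(seq_len(nBits),
         function(j) as.numeric(bitwAnd(idx, bitwShiftL(1L, j - 1L)) != 0L),
         numeric(n))
}

# ---- layer configuration and kernel generation ------------------------

#' Initialize angles for a bank of VQCs
#'
#' Rotation angles are drawn uniformly from \[0, 1) radians — away from
#' zero, where the circuit would sit at the uniform-state fixed point and
#' gradients could vanish.
#'
#' @param circuit a [`CircuitSpec-class`].
#' @param nVQCs number of circuits.
#' @return numeric matrix `(nAngles(circuit), nVQCs)`.
#' @export
initAngles <- function(circuit, nVQCs) {
  matrix(stats::runif(nAngles(circuit) * nVQCs), nAngles(circuit), nVQCs)
}

#' Configure a quantum-parameter-generated convolution layer
#'
#' @param plan an [`AllocationPlan-class`] (or `NULL` to build one from
#'   `cIn`, `cOut`, `kH`, `kW`).
#' @param circuit a [`CircuitSpec-class`] sized at `plan@qubitsPerVQC`
#'   qubits; defaults to a single `ry_rx` block.
#' @param strategy post-processing strategy: `"sst"` (default), `"rce"`,
#'   or `"lpp"`.
#' @param angles angle matrix `(nAngles(circuit), nVQCs)`; defaults to
#'   uniform \[0, 1) initialization.
#' @param head LPP head (list with `w`, `b`); defaults to a small random
#'   head for `"lpp"`, ignored otherwise.
#' @param cIn,cOut,kH,kW layer dimensions, used when `plan` is `NULL`.
#' @return a [`QPGLayerConfig-class`].
#' @examples
#' cfg <- qpgLayerConfig(cIn = 4, cOut = 1, kH = 3)
#' dim(generateKernel(cfg))
#' @export
qpgLayerConfig <- function(plan = NULL, circuit = NULL,
                           strategy = c("sst", "rce", "lpp"),
                           angles = NULL, head = NULL,
                           cIn = NULL, cOut = NULL, kH = NULL, kW = kH) {
  strategy <- match.arg(strategy)
  if (is.null(plan)) plan <- allocateVQC(cIn, cOut, kH, kW)
  if (is.null(circuit)) circuit <- circuitSpec(plan@qubitsPerVQC)
  if (is.null(angles)) angles <- initAngles(circuit, plan@nVQCs)
  if (strategy == "lpp" && is.null(head))
    head <- list(w = c(1, stats::runif(plan@qubitsPerVQC, -0.1, 0.1)), b = 0)
  if (strategy != "lpp") head <- list()
  new("QPGLayerConfig", plan = plan, circuit = circuit,
      strategy = strategy, angles = angles, head = head)
}

# Born probabilities of a state matrix, renormalized per column so each
# circuit's probabilities sum to 1 exactly (the simulator is unitary, so
# the correction is at machine-epsilon scale but keeps fixed points exact)
.bornProbs <- function(S) {
  P <- Mod(S)^2
  P / matrix(colSums(P), nrow(P), ncol(P), byrow = TRUE)
}

# raw per-VQC outputs: value matrix (valuesPerVQC x nVQCs) after
# post-processing, plus whatever the backward pass needs
.qpgOutputs <- function(config, plan = .circuitPlan(config@circuit)) {
  S <- .runBatch(config@circuit, config@angles, plan)
  v <- config@plan@valuesPerVQC
  used <- seq_len(v)
  out <- switch(config@strategy,
    rce = Re(S[used, , drop = FALSE]),
    sst = (pi / 2) * (.bornProbs(S)[used, , drop = FALSE] - 0.5),
    lpp = {
      P <- .bornProbs(S)[used, , drop = FALSE]
      bits <- indexBits(v, config@plan@qubitsPerVQC)
      config@head$w[1L] * P +
        matrix(as.vector(bits %*% config@head$w[-1L]), v, ncol(S)) +
        config@head$b
    })
  list(values = out, psi = S)
}

#' Generate a convolution kernel from a layer's VQCs
#'
#' Runs every VQC of the layer, post-processes its outputs, and scatters
#' the first `max(cIn, cOut)` values along the non-target channel axis.
#' With the output axis as target, `W[ci, co, kh, kw]` is value `ci` of
#' the VQC owned by `(co, kh, kw)`; with the input axis as target the
#' roles swap.  Deterministic given the angles.
#'
#' @param config a [`QPGLayerConfig-class`].
#' @return numeric 4-D array of dim `(cIn, cOut, kH, kW)`.
#' @export
generateKernel <- function(config) {
  validObject(config)
  .kernelFromValues(config@plan, .qpgOutputs(config)$values)
}

# scatter the (values x nVQCs) matrix into the (cIn, cOut, kH, kW) array;
# VQC columns are ordered target-channel fastest, then kh, then kw
.kernelFromValues <- function(plan, values) {
  if (plan@targetAxis == "output") {
    W <- array(values[seq_len(plan@cIn), , drop = FALSE],
               dim = c(plan@cIn, plan@cOut, plan@kH, plan@kW))
  } else {
    Wt <- array(values[seq_len(plan@cOut), , drop = FALSE],
                dim = c(plan@cOut, plan@cIn, plan@kH, plan@kW))
    W <- aperm(Wt, c(2L, 1L, 3L, 4L))
  }
  W
}

# inverse of .kernelFromValues: gather dL/dW into (values x nVQCs), with
# zero rows for the truncated basis tail
.valuesFromKernel <- function(plan, dW) {
  G <- matrix(0, plan@valuesPerVQC, plan@nVQCs)
  if (plan@targetAxis == "output") {
    G[seq_len(plan@cIn), ] <- matrix(dW, plan@cIn, plan@nVQCs)
  } else {
    G[seq_len(plan@cOut), ] <- matrix(aperm(dW, c(2L, 1L, 3L, 4L)),
                                      plan@cOut, plan@nVQCs)
  }
  G
}

# backward through kernel generation: dL/dW -> gradient on angles (and on
# the LPP head).  Analytic forward-mode circuit derivatives, batched over
# all VQCs: one extra circuit run per angle slot.
.qpgKernelBackward <- function(config, dW, cache = NULL,
                               plan = .circuitPlan(config@circuit)) {
  pl <- config@plan
  G <- .valuesFromKernel(pl, dW)               # dL/dy, (values x nVQCs)
  psi <- if (is.null(cache)) .runBatch(config@circuit, config@angles, plan)
         else cache$psi
  used <- seq_len(pl@valuesPerVQC)
  nAng <- nrow(config@angles)
  dAngles <- matrix(0, nAng, pl@nVQCs)
  headGrad <- NULL
  if (config@strategy == "rce") {
    # dL/dRe(psi_i); derivative states give Re(dpsi) directly
    Gfull <- matrix(0, nrow(psi), pl@nVQCs)
    Gfull[used, ] <- G
    for (j in seq_len(nAng)) {
      dpsi <- .derivBatch(config@circuit, config@angles, j, plan)
      dAngles[j, ] <- colSums(Gfull * Re(dpsi))
    }
  } else {
    # probability-based strategies: dL/dp = s * dL/dy with a constant s
    s <- if (config@strategy == "sst") pi / 2 else config@head$w[1L]
    Gp <- matrix(0, nrow(psi), pl@nVQCs)
    Gp[used, ] <- s * G
    for (j in seq_len(nAng)) {
      dpsi <- .derivBatch(config@circuit, config@angles, j, plan)
      dAngles[j, ] <- colSums(Gp * (2 * Re(Conj(psi) * dpsi)))
    }
    if (config@strategy == "lpp") {
      P <- .bornProbs(psi)[used, , drop = FALSE]
      bits <- indexBits(pl@valuesPerVQC, pl@qubitsPerVQC)
      headGrad <- list(
        w = c(sum(G * P), as.vector(crossprod(bits, rowSums(G)))),
        b = sum(G))
    }
  }
  list(angles = dAngles, head = headGrad)
}
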