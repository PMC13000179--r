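#' @import methods
NULL

#' Geometry of the variational quantum circuit ansatz
#'
#' A `CircuitSpec` fixes the shape of one variational quantum circuit (VQC):
#' `N` qubits, a Hadamard layer that puts every qubit into the uniform
#' superposition, then `K` repeated strongly-entangled blocks.  Each block
#' applies a layer of RY rotations, a layer of RX rotations, and an
#' entangling layer of CNOTs.  Only the rotation angles are trainable.
#'
#' The `rotations` mode controls how many trainable rotation gates each
#' block carries per qubit:
#' \describe{
#'   \item{`ry_rx`}{one RY and one RX per qubit (the default ansatz);}
#'   \item{`ry_only`}{one RY per qubit;}
#'   \item{`ry_single`}{a single RY on qubit 1 for the whole block — the
#'     minimal ansatz, one trainable gate per circuit when `nBlocks = 1`.}
#' }
#'
#' The entangling layer is a ring of CNOTs (control `j`, target `j + 1`,
#' with the last CNOT wrapping around to qubit 1); `chain` drops the
#' wrap-around and `none` drops the layer.  A single-qubit circuit has no
#' pair to entangle, so `entangler` is forced to `"none"` when
#' `nQubits == 1`.
#'
#' Basis-state index convention: index `i` (0-based) has qubit 1 as its
#' least-significant bit.
#'
#' @slot nQubits integer, number of qubits (N >= 1).
#' @slot nBlocks integer, number of repeated variational blocks (K >= 1).
#' @slot entangler character, one of `"ring"`, `"chain"`, `"none"`.
#' @slot rotations character, one of `"ry_rx"`, `"ry_only"`, `"ry_single"`.
#' @seealso [circuitSpec()], [runCircuit()], [anglesPerBlock()]
#' @exportClass CircuitSpec
setClass("CircuitSpec",
  representation(
    nQubits = "integer",
    nBlocks = "integer",
    entangler = "character",
    rotations = "character"
  )
)

setValidity("CircuitSpec", function(object) {
  msgs <- character(0)
  if (length(object@nQubits) != 1L || is.na(object@nQubits) || object@nQubits < 1L)
    msgs <- c(msgs, "nQubits must be a single integer >= 1")
  if (length(object@nBlocks) != 1L || is.na(object@nBlocks) || object@nBlocks < 1L)
    msgs <- c(msgs, "nBlocks must be a single integer >= 1")
  if (!object@entangler %in% c("ring", "chain", "none"))
    msgs <- c(msgs, "entangler must be one of 'ring', 'chain', 'none'")
  if (!object@rotations %in% c("ry_rx", "ry_only", "ry_single"))
    msgs <- c(msgs, "rotations must be one of 'ry_rx', 'ry_only', 'ry_single'")
  if (length(msgs) == 0L && object@nQubits == 1L && object@entangler != "none")
    msgs <- c(msgs, "entangler must be 'none' when nQubits == 1")
  if (length(msgs)) msgs else TRUE
})

#' Channel-axis allocation plan for quantum parameter generation
#'
#' Describes how the kernel of a convolution layer with `cIn` input
#' channels, `cOut` output channels and a `kH` x `kW` spatial footprint is
#' partitioned across independent VQCs.  The smaller of the two channel
#' axes is the *target* axis: one VQC is allocated per target channel and
#' kernel position, and each VQC emits one weight value per channel of the
#' larger (non-target) axis.  Each VQC therefore needs
#' `ceiling(log2(max(cIn, cOut)))` qubits (floor of 1), reading its values
#' off the first `max(cIn, cOut)` basis states.
#'
#' @slot cIn,cOut integer, input/output channel counts.
#' @slot kH,kW integer, kernel height/width.
#' @slot targetAxis character, `"input"` when `cIn <= cOut` else `"output"`.
#' @slot nVQCs integer, `min(cIn, cOut) * kH * kW`.
#' @slot qubitsPerVQC integer, qubits per circuit.
#' @slot valuesPerVQC integer, weight values read from each circuit.
#' @seealso [allocateVQC()], [countTrainable()]
#' @exportClass AllocationPlan
setClass("AllocationPlan",
  representation(
    cIn = "integer", cOut = "integer", kH = "integer", kW = "integer",
    targetAxis = "character", nVQCs = "integer",
    qubitsPerVQC = "integer", valuesPerVQC = "integer"
  )
)

setValidity("AllocationPlan", function(object) {
  msgs <- character(0)
  dims <- c(object@cIn, object@cOut, object@kH, object@kW)
  if (any(is.na(dims)) || any(dims < 1L))
    msgs <- c(msgs, "all layer dimensions must be integers >= 1")
  if (!object@targetAxis %in% c("input", "output"))
    msgs <- c(msgs, "targetAxis must be 'input' or 'output'")
  if (length(msgs) == 0L) {
    expectAxis <- if (object@cIn <= object@cOut) "input" else "output"
    if (object@targetAxis != expectAxis)
      msgs <- c(msgs, "targetAxis inconsistent with channel counts")
    if (object@nVQCs != min(object@cIn, object@cOut) * object@kH * object@kW)
      msgs <- c(msgs, "nVQCs must equal min(cIn, cOut) * kH * kW")
    if (object@valuesPerVQC != max(object@cIn, object@cOut))
      msgs <- c(msgs, "valuesPerVQC must equal max(cIn, cOut)")
    if (object@qubitsPerVQC != max(1L, as.integer(ceiling(log2(object@valuesPerVQC)))))
      msgs <- c(msgs, "qubitsPerVQC must be ceiling(log2(valuesPerVQC)), floor 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Configuration of one quantum-parameter-generated convolution layer
#'
#' Bundles the allocation plan, the shared circuit geometry, the
#' post-processing strategy, and the per-VQC rotation angles.  Angles are
#' stored as a matrix with one column per VQC and one row per trainable
#' rotation, ordered block by block, RY gates (qubit 1..N) before RX gates.
#' For the `"lpp"` strategy a single linear head (weight vector of length
#' `qubitsPerVQC + 1` plus a bias) is shared across all VQCs of the layer,
#' so its parameter overhead is bounded by `qubitsPerVQC + 2`.
#'
#' @slot plan an [`AllocationPlan-class`].
#' @slot circuit a [`CircuitSpec-class`] shared by all the layer's VQCs.
#' @slot strategy character, `"rce"`, `"lpp"`, or `"sst"`.
#' @slot angles numeric matrix, `anglesPerBlock(circuit) * nBlocks` rows,
#'   `nVQCs` columns, radians.
#' @slot head list with components `w` (length `qubitsPerVQC + 1`) and `b`
#'   (scalar) for `"lpp"`; empty list otherwise.
#' @seealso [qpgLayerConfig()], [generateKernel()]
#' @exportClass QPGLayerConfig
setClass("QPGLayerConfig",
  representation(
    plan = "AllocationPlan",
    circuit = "CircuitSpec",
    strategy = "character",
    angles = "matrix",
    head = "list"
  )
)

setValidity("QPGLayerConfig", function(object) {
  msgs <- character(0)
  if (!object@strategy %in% c("rce", "lpp", "sst"))
    msgs <- c(msgs, "strategy must be 'rce', 'lpp' or 'sst'")
  nAng <- anglesPerBlock(object@circuit) * object@circuit@nBlocks
  if (nrow(object@angles) != nAng || ncol(object@angles) != object@plan@nVQCs)
    msgs <- c(msgs, sprintf(
      "angles must be a %d x %d matrix (rotations x VQCs)",
      nAng, object@plan@nVQCs))
  if (!all(is.finite(object@angles)))
    msgs <- c(msgs, "angles must be finite")
  if (identical(object@strategy, "lpp")) {
    if (!all(c("w", "b") %in% names(object@head)) ||
        length(object@head$w) != object@plan@qubitsPerVQC + 1L ||
        length(object@head$b) != 1L)
      msgs <- c(msgs, "lpp head must have w of length qubitsPerVQC + 1 and scalar b")
  }
  if (length(msgs)) msgs else TRUE
})

#' Sample-wise segmentation metrics report
#'
#' Holds per-sample intersection-over-union and Dice similarity values plus
#' their mean and population standard deviation.  Every sample enters with
#' equal weight, so small targets count as much as large ones.
#'
#' @slot iou,dsc numeric vectors of per-sample values in \[0, 1\].
#' @seealso [aggregateMetrics()], [iou()], [dsc()]
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(iou = "numeric", dsc = "numeric")
)

setValidity("MetricsReport", function(object) {
  msgs <- character(0)
  if (length(object@iou) < 1L || length(object@iou) != length(object@dsc))
    msgs <- c(msgs, "iou and dsc must be nonempty vectors of equal length")
  else {
    if (any(object@iou < 0 | object@iou > 1 | object@dsc < 0 | object@dsc > 1))
      msgs <- c(msgs, "metric values must lie in [0, 1]")
    if (any(object@dsc < object@iou - 1e-12))
      msgs <- c(msgs, "DSC must be >= IoU for every sample")
  }
  if (length(msgs)) msgs else TRUE
})

#' One synthetic organ/tumor segmentation sample
#'
#' A single-channel image in \[0, 1\] with two nested binary masks: a
#' smooth elliptical "organ" and a smaller irregular "tumor" contained in
#' it.  Generation is fully determined by `seed`.
#'
#' @slot image numeric matrix, intensities in \[0, 1\].
#' @slot organMask,tumorMask 0/1 integer matrices of the same shape;
#'   `tumorMask` is a subset of `organMask`.
#' @slot seed integer provenance seed.
#' @seealso [generateSegSample()], [buildDataset()]
#' @exportClass SegmentationSample
setClass("SegmentationSample",
  representation(
    image = "matrix", organMask = "matrix", tumorMask = "matrix",
    seed = "integer"
  )
)

setValidity("SegmentationSample", function(object) {
  msgs <- character(0)
  d <- dim(object@image)
  if (!identical(d, dim(object@organMask)) || !identical(d, dim(object@tumorMask)))
    msgs <- c(msgs, "image and masks must share one spatial shape")
  if (any(object@image < 0 | object@image > 1))
    msgs <- c(msgs, "image values must lie in [0, 1]")
  if (!all(object@organMask %in% c(0, 1)) || !all(object@tumorMask %in% c(0, 1)))
    msgs <- c(msgs, "masks must be 0/1 valued")
  if (any(object@tumorMask == 1 & object@organMask == 0))
    msgs <- c(msgs, "tumorMask must be contained in organMask")
  if (length(msgs)) msgs else TRUE
})

#' Miniature hybrid segmentation model
#'
#' An encoder-decoder convolutional network for binary segmentation whose
#' six named components (`encoder1`, `block1`, `block2`, `dblock1`,
#' `dblock2`, `finalconv`) can each be trained classically or through
#' quantum parameter generation, as dictated by a scheme.
#'
#' @slot layers list of internal layer states (weights, angles, geometry).
#' @slot components character, the component names carrying QPG layers.
#' @slot scheme integer scheme id (0 = fully classical).
#' @slot strategy character post-processing strategy of the QPG layers.
#' @slot inputSize integer, side length of the (square) input images.
#' @slot widths integer vector of encoder stage widths.
#' @seealso [buildSegModel()], [segForward()], [trainModel()]
#' @exportClass HybridSegModel
setClass("HybridSegModel",
  representation(
    layers = "list",
    components = "character",
    scheme = "integer",
    strategy = "character",
    inputSize = "integer",
    widths = "integer"
  )
)
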