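#' @rdname accessors
#' @export
setGeneric("nQubits", function(x) standardGeneric("nQubits"))
#' @rdname accessors
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))
#' @rdname accessors
#' @export
setGeneric("nVQCs", function(x) standardGeneric("nVQCs"))
#' @rdname accessors
#' @export
setGeneric("qubitsPerVQC", function(x) standardGeneric("qubitsPerVQC"))
#' @rdname accessors
#' @export
setGeneric("valuesPerVQC", function(x) standardGeneric("valuesPerVQC"))
#' @rdname accessors
#' @export
setGeneric("targetAxis", function(x) standardGeneric("targetAxis"))
#' @rdname accessors
#' @export
setGeneric("strategy", function(x) standardGeneric("strategy"))
#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))
#' @rdname accessors
#' @export
setGeneric("angles<-", function(x, value) standardGeneric("angles<-"))
#' @rdname accessors
#' @export
setGeneric("iouValues", function(x) standardGeneric("iouValues"))
#' @rdname accessors
#' @export
setGeneric("dscValues", function(x) standardGeneric("dscValues"))
#' @rdname accessors
#' @export
setGeneric("sampleImage", function(x) standardGeneric("sampleImage"))
#' @rdname accessors
#' @export
setGeneric("organMask", function(x) standardGeneric("organMask"))
#' @rdname accessors
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))

#' Accessors for qpgnet S4 objects
#'
#' Small accessor generics so user code never touches slots directly:
#' circuit geometry (`nQubits`, `nBlocks`), allocation facts (`nVQCs`,
#' `qubitsPerVQC`, `valuesPerVQC`, `targetAxis`), layer configuration
#' (`strategy`, `angles`, `angles<-`), metric vectors (`iouValues`,
#' `dscValues`), and sample components (`sampleImage`, `organMask`,
#' `tumorMask`).
#'
#' @param x the object.
#' @param value replacement value.
#' @return the requested component.
#' @name accessors
#' @aliases nQubits,CircuitSpec-method nBlocks,CircuitSpec-method
NULL

setMethod("nQubits", "CircuitSpec", function(x) x@nQubits)
setMethod("nBlocks", "CircuitSpec", function(x) x@nBlocks)
setMethod("nVQCs", "AllocationPlan", function(x) x@nVQCs)
setMethod("qubitsPerVQC", "AllocationPlan", function(x) x@qubitsPerVQC)
setMethod("valuesPerVQC", "AllocationPlan", function(x) x@valuesPerVQC)
setMethod("targetAxis", "AllocationPlan", function(x) x@targetAxis)
setMethod("nVQCs", "QPGLayerConfig", function(x) x@plan@nVQCs)
setMethod("qubitsPerVQC", "QPGLayerConfig", function(x) x@plan@qubitsPerVQC)
setMethod("strategy", "QPGLayerConfig", function(x) x@strategy)
setMethod("angles", "QPGLayerConfig", function(x) x@angles)
setMethod("angles<-", "QPGLayerConfig", function(x, value) {
  x@angles <- value
  validObject(x)
  x
})
setMethod("iouValues", "MetricsReport", function(x) x@iou)
setMethod("dscValues", "MetricsReport", function(x) x@dsc)
setMethod("sampleImage", "SegmentationSample", function(x) x@image)
setMethod("organMask", "SegmentationSample", function(x) x@organMask)
setMethod("tumorMask", "SegmentationSample", function(x) x@tumorMask)

setMethod("show", "CircuitSpec", function(object) {
  cat(sprintf(
    "CircuitSpec: %d qubit(s), %d block(s), entangler '%s', rotations '%s'\n",
    object@nQubits, object@nBlocks, object@entangler, object@rotations))
  cat(sprintf("  trainable rotations per circuit: %d\n",
              anglesPerBlock(object) * object@nBlocks))
})

setMethod("show", "AllocationPlan", function(object) {
  cat(sprintf("AllocationPlan for %d -> %d channels, %dx%d kernel\n",
              object@cIn, object@cOut, object@kH, object@kW))
  cat(sprintf("  target axis: %s\n  VQCs: %d (%d qubit(s) each, %d value(s) read)\n",
              object@targetAxis, object@nVQCs, object@qubitsPerVQC,
              object@valuesPerVQC))
})

setMethod("show", "QPGLayerConfig", function(object) {
  show(object@plan)
  cat(sprintf("  strategy: %s\n", toupper(object@strategy)))
  show(object@circuit)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d sample(s)\n", length(object@iou)))
  cat(sprintf("  IoU: mean %.4f, sd %.4f\n  DSC: mean %.4f, sd %.4f\n",
              mean(object@iou), popSD(object@iou),
              mean(object@dsc), popSD(object@dsc)))
})

setMethod("show", "SegmentationSample", function(object) {
  d <- dim(object@image)
  cat(sprintf(
    "SegmentationSample %dx%d (seed %d): organ %.1f%%, tumor %.1f%% of pixels\n",
    d[1], d[2], object@seed,
    100 * mean(object@organMask), 100 * mean(object@tumorMask)))
})

setMethod("show", "HybridSegModel", function(object) {
  cat(sprintf(
    "HybridSegModel (scheme %d, strategy %s, input %dx%d)\n",
    object@scheme, toupper(object@strategy),
    object@inputSize, object@inputSize))
  print(parameterReport(object))
})
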