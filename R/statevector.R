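#' Construct a circuit specification
#'
#' @param nQubits number of qubits (N >= 1).
#' @param nBlocks number of repeated variational blocks (K >= 1).
#' @param entangler entangling layer: `"ring"` (CNOT chain with
#'   wrap-around, the default), `"chain"`, or `"none"`.  Forced to
#'   `"none"` for a single qubit.
#' @param rotations rotation layout per block: `"ry_rx"` (default),
#'   `"ry_only"`, or the minimal `"ry_single"`.
#' @return a [`CircuitSpec-class`] object.
#' @examples
#' circuitSpec(3, 1)
#' @export
circuitSpec <- function(nQubits, nBlocks = 1L,
                        entangler = c("ring", "chain", "none"),
                        rotations = c("ry_rx", "ry_only", "ry_single")) {
  entangler <- match.arg(entangler)
  rotations <- match.arg(rotations)
  nQubits <- as.integer(nQubits)
  nBlocks <- as.integer(nBlocks)
  if (length(nQubits) != 1L || is.na(nQubits) || nQubits < 1L)
    stop("nQubits must be a single integer >= 1")
  if (length(nBlocks) != 1L || is.na(nBlocks) || nBlocks < 1L)
    stop("nBlocks must be a single integer >= 1")
  if (nQubits == 1L) entangler <- "none"
  new("CircuitSpec", nQubits = nQubits, nBlocks = nBlocks,
      entangler = entangler, rotations = rotations)
}

#' Number of trainable rotation angles per block
#'
#' @param spec a [`CircuitSpec-class`].
#' @return integer: `2 * nQubits` for `"ry_rx"`, `nQubits` for
#'   `"ry_only"`, `1` for `"ry_single"`.
#' @export
anglesPerBlock <- function(spec) {
  switch(spec@rotations,
    ry_rx = 2L * spec@nQubits,
    ry_only = spec@nQubits,
    ry_single = 1L
  )
}

#' Total trainable rotation angles of one circuit
#' @param spec a [`CircuitSpec-class`].
#' @return integer `anglesPerBlock(spec) * nBlocks(spec)`.
#' @export
nAngles <- function(spec) anglesPerBlock(spec) * spec@nBlocks

#' Elementary gate matrices
#'
#' Returns the unitary matrix of a named gate, mainly for verification
#' (gate-algebra identities, dense-matrix circuit oracles).
#'
#' @param name `"h"`, `"ry"`, `"rx"`, or `"cnot"`.
#' @param theta rotation angle in radians (rotation gates only).
#' @return a complex matrix (2x2, or 4x4 for `"cnot"` with qubit 1 as
#'   control and qubit 2 as target in the least-significant-bit-first
#'   convention).
#' @export
gateMatrix <- function(name = c("h", "ry", "rx", "cnot"), theta = NULL) {
  name <- match.arg(name)
  switch(name,
    h = matrix(complex(real = c(1, 1, 1, -1) / sqrt(2)), 2, 2),
    ry = {
      c2 <- cos(theta / 2); s2 <- sin(theta / 2)
      matrix(complex(real = c(c2, s2, -s2, c2)), 2, 2)
    },
    rx = {
      c2 <- cos(theta / 2); s2 <- sin(theta / 2)
      matrix(c(complex(real = c2), complex(imaginary = -s2),
               complex(imaginary = -s2), complex(real = c2)), 2, 2)
    },
    cnot = {
      # basis order |00>,|01>,|10>,|11> with qubit 1 (control) as LSB:
      # |01> (control set) swaps with |11>
      m <- diag(4) + 0i
      m[, c(1, 4, 3, 2)]
    }
  )
}

# ---- internal batched statevector engine ------------------------------
# States live in a complex matrix of dim (2^N, M): one column per circuit.
# Basis index i (0-based) has qubit 1 as the least-significant bit.

# index pairs for a single-qubit gate on `qubit`: rows where the bit is 0
.qubitPairs <- function(nQubits, qubit) {
  stride <- bitwShiftL(1L, qubit - 1L)
  idx <- 0:(2L^nQubits - 1L)
  i0 <- idx[bitwAnd(idx, stride) == 0L]
  list(i0 = i0 + 1L, i1 = i0 + stride + 1L)
}

# permutation implementing CNOT(control, target): rows with the control
# bit set get their target bit flipped
.cnotPerm <- function(nQubits, control, target) {
  idx <- 0:(2L^nQubits - 1L)
  cbit <- bitwShiftL(1L, control - 1L)
  tbit <- bitwShiftL(1L, target - 1L)
  src <- ifelse(bitwAnd(idx, cbit) != 0L, bitwXor(idx, tbit), idx)
  src + 1L
}

# static per-geometry plan: qubit pair indices, entangler permutations,
# and the (block, axis, qubit) meaning of every angle row
.circuitPlan <- function(spec) {
  n <- spec@nQubits
  pairs <- lapply(seq_len(n), function(q) .qubitPairs(n, q))
  ent <- NULL
  if (spec@entangler != "none" && n >= 2L) {
    cps <- if (spec@entangler == "ring") {
      lapply(seq_len(n), function(j) c(j, if (j < n) j + 1L else 1L))
    } else {
      lapply(seq_len(n - 1L), function(j) c(j, j + 1L))
    }
    ent <- lapply(cps, function(ct) .cnotPerm(n, ct[1], ct[2]))
  }
  rotQubits <- switch(spec@rotations,
    ry_rx = seq_len(n), ry_only = seq_len(n), ry_single = 1L)
  hasRX <- identical(spec@rotations, "ry_rx")
  list(pairs = pairs, ent = ent, rotQubits = rotQubits, hasRX = hasRX)
}

# one rotation layer on `qubit` for all columns; theta is length-M
.applyRot <- function(S, pair, theta, axis) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  A <- S[pair$i0, , drop = FALSE]
  B <- S[pair$i1, , drop = FALSE]
  nr <- nrow(A); nc <- ncol(A)
  C <- matrix(c2, nr, nc, byrow = TRUE)
  Sm <- matrix(s2, nr, nc, byrow = TRUE)
  if (axis == "y") {
    S[pair$i0, ] <- C * A - Sm * B
    S[pair$i1, ] <- Sm * A + C * B
  } else {
    S[pair$i0, ] <- C * A - (0+1i) * Sm * B
    S[pair$i1, ] <- (0-1i) * Sm * A + C * B
  }
  S
}

# run M circuits sharing one geometry; angMat is (nAngles x M)
.runBatch <- function(spec, angMat, plan = .circuitPlan(spec)) {
  n <- spec@nQubits
  M <- ncol(angMat)
  dimS <- 2L^n
  S <- matrix(complex(real = 2^(-n / 2)), dimS, M)
  row <- 0L
  for (k in seq_len(spec@nBlocks)) {
    for (q in plan$rotQubits) {
      row <- row + 1L
      S <- .applyRot(S, plan$pairs[[q]], angMat[row, ], "y")
    }
    if (plan$hasRX) {
      for (q in plan$rotQubits) {
        row <- row + 1L
        S <- .applyRot(S, plan$pairs[[q]], angMat[row, ], "x")
      }
    }
    if (!is.null(plan$ent)) for (perm in plan$ent) S <- S[perm, , drop = FALSE]
  }
  S
}

# forward-mode derivative states: d psi / d theta_j equals half the state
# of the same circuit with theta_j advanced by pi (Pauli-rotation algebra)
.derivBatch <- function(spec, angMat, j, plan = .circuitPlan(spec)) {
  shifted <- angMat
  shifted[j, ] <- shifted[j, ] + pi
  0.5 * .runBatch(spec, shifted, plan)
}

.canonicalAngles <- function(spec, angles) {
  nAng <- nAngles(spec)
  if (is.matrix(angles)) {
    if (nrow(angles) == spec@nBlocks && ncol(angles) == anglesPerBlock(spec))
      angles <- as.vector(t(angles))
    else angles <- as.vector(angles)
  }
  if (length(angles) != nAng)
    stop(sprintf("angle count mismatch: expected %d, got %d",
                 nAng, length(angles)))
  if (!all(is.finite(angles))) stop("angles must be finite")
  as.numeric(angles)
}

# ---- public single-circuit API ----------------------------------------

#' Uniform superposition produced by the Hadamard layer
#'
#' @param spec a [`CircuitSpec-class`].
#' @return complex vector of `2^nQubits` amplitudes, all equal to
#'   `2^(-nQubits/2)`.
#' @examples
#' initialSuperposition(circuitSpec(2))
#' @export
initialSuperposition <- function(spec) {
  rep(complex(real = 2^(-spec@nQubits / 2)), 2L^spec@nQubits)
}

#' Run one variational circuit exactly
#'
#' Applies the Hadamard layer, then for each block an RY layer, an RX
#' layer (ansatz permitting) and the entangling CNOT layer, in that order.
#'
#' @param spec a [`CircuitSpec-class`].
#' @param angles numeric vector of length `nAngles(spec)` (block-major,
#'   RY angles for qubits 1..N then RX angles), or a matrix with one row
#'   per block.
#' @return complex amplitude vector of length `2^nQubits`, unit norm.
#' @examples
#' runCircuit(circuitSpec(1), c(pi / 2, 0))
#' @export
runCircuit <- function(spec, angles) {
  angles <- .canonicalAngles(spec, angles)
  as.vector(.runBatch(spec, matrix(angles, ncol = 1L)))
}

#' Measurement probabilities of a statevector
#'
#' Born-rule probabilities `p_i = |psi_i|^2`, computed exactly from the
#' simulated amplitudes (no shot sampling).
#'
#' @param state complex amplitude vector.
#' @return numeric vector of probabilities summing to 1 for a normalized
#'   state.
#' @export
probabilities <- function(state) Mod(state)^2

#' Draw measurement shots from a statevector
#'
#' Optional finite-shot sampling mode for experimentation; parameter
#' generation always uses the exact probabilities.
#'
#' @param state complex amplitude vector.
#' @param nShots number of measurement shots.
#' @return integer vector of basis-state counts summing to `nShots`.
#' @export
sampleShots <- function(state, nShots) {
  p <- probabilities(state)
  as.integer(stats::rmultinom(1L, nShots, p / sum(p)))
}

#' Gradient of a measurement probability via the parameter-shift rule
#'
#' Evaluates `dp[outputIndex] / d angles[wrtAngle]` from two circuit runs
#' with the angle shifted by +/- pi/2.  Exact for this ansatz (all
#' trainable gates are Pauli rotations); serves as a verification path
#' against the analytic gradient used in training.
#'
#' @param spec a [`CircuitSpec-class`].
#' @param angles angle vector (see [runCircuit()]).
#' @param outputIndex 1-based basis-state index in `1..2^nQubits`.
#' @param wrtAngle 1-based angle index in `1..nAngles(spec)`.
#' @return the scalar derivative.
#' @export
gradParamShift <- function(spec, angles, outputIndex, wrtAngle) {
  angles <- .canonicalAngles(spec, angles)
  if (outputIndex < 1L || outputIndex > 2L^spec@nQubits)
    stop("outputIndex out of range")
  if (wrtAngle < 1L || wrtAngle > length(angles))
    stop("wrtAngle out of range")
  up <- angles; up[wrtAngle] <- up[wrtAngle] + pi / 2
  dn <- angles; dn[wrtAngle] <- dn[wrtAngle] - pi / 2
  (probabilities(runCircuit(spec, up))[outputIndex] -
     probabilities(runCircuit(spec, dn))[outputIndex]) / 2
}

#' Full probability Jacobian of a circuit
#'
#' Computes `dp_i / d theta_j` for all basis states i and trainable angles
#' j, either analytically in forward mode (the derivative of a Pauli
#' rotation is half the same gate advanced by pi, so each column costs one
#' extra circuit run) or by the parameter-shift rule.
#'
#' @param spec a [`CircuitSpec-class`].
#' @param angles angle vector (see [runCircuit()]).
#' @param method `"analytic"` (default) or `"shift"`.
#' @return numeric matrix of dim `(2^nQubits, nAngles(spec))`.
#' @export
circuitProbJacobian <- function(spec, angles, method = c("analytic", "shift")) {
  method <- match.arg(method)
  angles <- .canonicalAngles(spec, angles)
  nAng <- length(angles)
  plan <- .circuitPlan(spec)
  angMat <- matrix(angles, ncol = 1L)
  J <- matrix(0, 2L^spec@nQubits, nAng)
  if (method == "analytic") {
    psi <- .runBatch(spec, angMat, plan)
    for (j in seq_len(nAng)) {
      dpsi <- .derivBatch(spec, angMat, j, plan)
      J[, j] <- 2 * Re(Conj(psi) * dpsi)
    }
  } else {
    for (j in seq_len(nAng)) {
      up <- angMat; up[j, ] <- up[j, ] + pi / 2
      dn <- angMat; dn[j, ] <- dn[j, ] - pi / 2
      J[, j] <- (Mod(.runBatch(spec, up, plan))^2 -
                   Mod(.runBatch(spec, dn, plan))^2) / 2
    }
  }
  J
}
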