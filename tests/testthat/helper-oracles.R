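# Independent oracles used across the suite.  They share no code with
# the package's computational paths: the circuit oracle multiplies dense
# Kronecker-product gate matrices, the convolution oracle is a nested
# loop, and gradients are checked by central finite differences.

# dense-matrix statevector oracle (qubit 1 = least-significant bit, so a
# single-qubit gate on qubit q sits at position q from the right of the
# Kronecker chain)
oracleCircuit <- function(spec, ang) {
  N <- nQubits(spec)
  I2 <- diag(2) + 0i
  kronChain <- function(mats) Reduce(kronecker, rev(mats))
  gate1 <- function(q, m) {
    l <- rep(list(I2), N)
    l[[q]] <- m
    kronChain(l)
  }
  cnotN <- function(ctrl, tgt) {
    M <- matrix(0 + 0i, 2^N, 2^N)
    for (i in 0:(2^N - 1)) {
      j <- if (bitwAnd(i, bitwShiftL(1L, ctrl - 1L)) > 0)
        bitwXor(i, bitwShiftL(1L, tgt - 1L)) else i
      M[j + 1, i + 1] <- 1
    }
    M
  }
  psi <- rep(0 + 0i, 2^N); psi[1] <- 1
  for (q in 1:N) psi <- gate1(q, gateMatrix("h")) %*% psi
  rotQ <- if (spec@rotations == "ry_single") 1L else seq_len(N)
  row <- 0L
  for (k in seq_len(nBlocks(spec))) {
    for (q in rotQ) {
      row <- row + 1L
      psi <- gate1(q, gateMatrix("ry", ang[row])) %*% psi
    }
    if (spec@rotations == "ry_rx") for (q in rotQ) {
      row <- row + 1L
      psi <- gate1(q, gateMatrix("rx", ang[row])) %*% psi
    }
    if (spec@entangler == "ring" && N >= 2)
      for (j in 1:N) psi <- cnotN(j, if (j < N) j + 1L else 1L) %*% psi
    if (spec@entangler == "chain" && N >= 2)
      for (j in 1:(N - 1)) psi <- cnotN(j, j + 1L) %*% psi
  }
  as.vector(psi)
}

# nested-loop cross-correlation oracle (stride 1, zero padding `pad`)
naiveConv <- function(x, W, pad) {
  d <- dim(x); kd <- dim(W)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  Ho <- d[1] + 2 * pad - kd[3] + 1
  Wo <- d[2] + 2 * pad - kd[4] + 1
  out <- array(0, c(Ho, Wo, kd[2], d[4]))
  for (b in seq_len(d[4])) for (co in seq_len(kd[2]))
    for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
      s <- 0
      for (ci in seq_len(kd[1])) for (dh in seq_len(kd[3]))
        for (dw in seq_len(kd[4]))
          s <- s + xp[i + dh - 1, j + dw - 1, ci, b] * W[ci, co, dh, dw]
      out[i, j, co, b] <- s
    }
  out
}

# central finite-difference probability gradient
fdProbGrad <- function(spec, ang, h = 1e-5) {
  vapply(seq_along(ang), function(j) {
    up <- ang; up[j] <- up[j] + h
    dn <- ang; dn[j] <- dn[j] - h
    (probabilities(runCircuit(spec, up)) -
       probabilities(runCircuit(spec, dn))) / (2 * h)
  }, numeric(2^nQubits(spec)))
}

# random binary mask of the given fill probability
randomMask <- function(n = 16, p = 0.3) {
  matrix(rbinom(n * n, 1, p), n, n)
}
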