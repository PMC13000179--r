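---
title: "Hybrid quantum-classical training of segmentation networks"
author: "qpgnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid quantum-classical training of segmentation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpgnet)
```

## The idea

Binary segmentation networks for organ-at-risk and tumor delineation are
routinely over-parameterized relative to the labeled data available in a
clinical setting.  `qpgnet` implements *quantum parameter generation*
(QPG): the kernel of a convolution layer is not stored and trained
directly, but produced on every forward pass by a bank of small
variational quantum circuits (VQCs), simulated exactly.  Only the
circuits' rotation angles are trainable, and a circuit over $N$ qubits
emits up to $2^N$ weight values, so the trainable count of a layer grows
with $\log_2$ of its channel width rather than linearly — the
quantum-side cost of a layer with $n$ generated weights is
$O(\mathrm{polylog}(n))$.

## The circuit ansatz

Each VQC applies a Hadamard layer (all qubits into the uniform
superposition), then $K$ repeated strongly-entangled blocks; each block
is an RY rotation layer, an RX rotation layer, and a ring of CNOTs
(control $j$, target $j + 1$, the last wrapping to qubit 1):

$$
|\psi_{\mathrm{final}}\rangle
  = \prod_{k=1}^{K}\Big[\;\prod_{j} \mathrm{CNOT}_{j,j+1}
  \cdot \bigotimes_i R_X(\theta_X^{ki})
  \cdot \bigotimes_i R_Y(\theta_Y^{ki})\Big]
  \; H^{\otimes N} |0\rangle^{\otimes N}.
$$

The written product of CNOTs over $j = 1..N$ only closes if it wraps
around, so the ring form is the default; a `chain` variant (no
wrap-around) and `none` are exposed for ablation, and a single-qubit
circuit has no entangling layer at all.  Basis state $i$ carries qubit 1
as its least-significant bit — a fixed convention used by the index
encodings below.

Measurement probabilities are exact statevector magnitudes,
renormalized per circuit so they sum to one exactly: the simulator is
unitary, so the correction is at machine-epsilon scale, but it makes
analytic fixed points (the uniform state, the zero SST kernel) exact
rather than merely within rounding.  A finite-shot sampling mode exists
for experimentation but is never used in parameter generation.

Three rotation layouts are supported per block: `ry_rx` (the default
pair above), `ry_only`, and a deliberately minimal `ry_single` — one RY
gate on qubit 1 per block.  The minimal mode exists because the
framework's minimum-parameter claim for a $4 \times 4 \times 1 \times 1$
kernel (4 trainable parameters for 16 generated weights) is only
realizable with one trainable rotation per circuit; the paired layout
would already use 4 angles per two-qubit circuit.

## From circuits to kernels

For a convolution with $C_{\mathrm{in}}$ input channels,
$C_{\mathrm{out}}$ output channels and a $K_h \times K_w$ footprint, the
smaller channel axis becomes the *target* axis (ties go to the input
axis).  One independent VQC is allocated per target channel and kernel
position — $\min(C_{\mathrm{in}}, C_{\mathrm{out}})\,K_h K_w$ circuits —
and each emits one weight per channel of the larger axis, so it needs
$\lceil \log_2 \max(C_{\mathrm{in}}, C_{\mathrm{out}}) \rceil$ qubits
(floor 1).  When the larger axis is not a power of two, the first basis
states are used and the tail is discarded: this is the smallest circuit
covering the axis, and it reproduces the worked qubit counts (nine
qubits for a 512-channel axis, eight for 256).  Keeping one circuit per
target channel preserves channel independence — perturbing one
circuit's angles moves only the kernel slice it owns — while the Born
rule bounds the probability mass each circuit can distribute over its
slice, a built-in weight-normalization-like property.

Quantum outputs live on the wrong scale for network weights, so a
post-processing map is applied:

* **RCE** — the real component of each amplitude, in $[-1, 1]$.
  Simulator-exact; on hardware it would need state tomography.
* **LPP** — a learned linear head applied to each probability
  concatenated with the binary encoding of its basis index
  ($d_0$ the least-significant bit).  One head is shared across all of
  a layer's circuits, so its overhead is bounded at
  `qubitsPerVQC + 2` parameters per layer; the ledger reports circuit
  and post-processing parameters separately because the headline counts
  quoted for the framework are circuit-only.
* **SST** — $y_i = \frac{\pi}{2}(p_i - 0.5) \in [-\pi/4, \pi/4]$, the
  default: negative weights at zero extra parameters.

`QPGConv` convolves with the generated kernel; `QPGAConv` adds the
generated kernel as an increment to a frozen base (adapter-style
fine-tuning, the base never receives gradient).  The low-rank baseline,
`ConvLoRA`, factorizes each kernel position's
$C_{\mathrm{out}} \times C_{\mathrm{in}}$ slice as $B A$ with rank $r$,
giving $r(C_{\mathrm{in}} + C_{\mathrm{out}})K_h K_w$ trainable values.
The per-position (rather than flattened-matrix) factorization is forced
by the published counts — $9216 = 8 \cdot (64 + 64) \cdot 9$ at rank 8,
where a flattened factorization would give 5120 — and no $\alpha/r$
scaling is applied.  Convolution throughout is the deep-learning
contract: cross-correlation, stride 1, "same" zero padding.

```{r counts}
countTrainable(allocateVQC(64, 1, 3, 3))$vqc    # vs classic 576
countTrainable(allocateVQC(64, 64, 3, 3))$vqc   # vs classic 36864
convLoRAParamCount(64, 64, 3, 3, rank = 8)
```

## Training

Training is hybrid: classical weights and circuit angles sit in one
Adam optimizer (learning rate 0.001, weight decay 5e-4, batch size 8,
20 epochs, no scheduler — the framework's stated defaults).  Every
forward pass regenerates the QPG kernels from the current angles; the
loss gradient flows back through the convolution into $\partial L /
\partial W$ and then analytically through the simulator: the derivative
of a Pauli rotation is half the same gate advanced by $\pi$, so each
angle slot of a layer costs one extra (batched) circuit run.  The
parameter-shift rule — the same derivative from runs at $\pm\pi/2$ —
is implemented as an independent verification path, and the test suite
requires analytic, shift, and finite-difference gradients to agree to
$10^{-6}$.

Angles initialize uniformly on $[0, 1)$ radians and classical weights
by fan-in variance scaling (Kaiming); neither starts at zero, where the
circuits would sit at the uniform-state fixed point with vanishing
gradients.  The loss is binary cross-entropy plus soft Dice (the
framework leaves the loss unstated; this is the standard pairing for
binary medical segmentation), predictions binarize at 0.5, and the best
epoch's test metrics are retained.  Per-sample IoU and DSC are averaged
with equal weight per sample, and the reported spread is the population
standard deviation (the divisor is unstated upstream; $n$ is used).
Empty-mask corner cases are defined as: both masks empty scores 1,
exactly one empty scores 0.

## The miniature model and its schemes

The full tokenized-MLP UNext is reduced to a faithful miniature that
exercises the framework at the convolution level: three 3×3 stages down
(`encoder1`, `block1`, `block2`; 2× max-pooling after the first two),
two 3×3 stages up (`dblock1`, `dblock2`; nearest-neighbour upsampling
and additive skip connections), and a 1×1 sigmoid head (`finalconv`).
Each conv stage except the head is followed by per-channel batch
normalization (conv → BN → ReLU).  BN is not optional here: SST
probabilities concentrate near $2^{-N}$, so freshly generated kernels
are strongly negative and un-normalized activations die at the ReLU.
BN parameters are always classical — QPG replaces kernels only.

The default widths (8, 16, 32) are chosen so that both branches of the
allocation rule occur (channel-up on the way down, channel-down on the
way up); the published architecture's exact widths are unstated, so the
miniature is a documented choice, not a reconstruction.  Eleven
integration schemes name which components train through QPG (scheme 3,
for instance, is `encoder1`, `block2`, `dblock2`; scheme 0 is the fully
classical control).

## Synthetic data

The generator emulates the preprocessing contract of a kidney-CT
segmentation corpus without downloading anything: single-channel images
in $[0,1]$, a smooth elliptical "organ" (5–30% of the frame, intensity
+0.35 over a 0.25 background), a smaller irregular "tumor" nested
inside it (+0.25 further, sinusoidally perturbed boundary), and
Gaussian pixel noise (sd 0.05).  Shape and noise draw from separate
seeded streams, so a sample's geometry is invariant to the noise
setting and everything is a bit-exact function of its seed.  Datasets
split 9:1, first samples to the training set; the tumor task first
crops the tight bounding box of the organ-tumor union and resizes back,
mirroring a region-of-interest pipeline.  The default desk-scale size
is 32×32 (256×256 is supported): at 32×32 a full training run is
minutes-scale on one CPU with simulated circuits.

What passing at desk scale shows — and does not.  The synthetic blobs
are high-contrast, single-instance, and noise-limited; real CT slices
carry anatomy, annotation ambiguity, and class imbalance the generator
does not emulate.  Tests passing here validate the machinery (exact
simulation, gradients, allocation, counting, the training loop), not
clinical segmentation quality; the published full-scale accuracy
comparisons on real data are out of scope by design.

```{r train, eval = FALSE}
ds <- buildDataset(200, size = 32, seed = 2026)
train <- stackSamples(ds$train, "organ")
test <- stackSamples(ds$test, "organ")
set.seed(701)
model <- buildSegModel(scheme = 3)
fit <- trainModel(model, train, test, trainConfig(epochs = 20, seed = 701))
fit$best
```

## Numerical choices and limitations

* Exact statevector simulation throughout; no shot noise or hardware
  noise models.  Circuits are batched per layer (one complex matrix per
  gate layer across all of a layer's VQCs), which is what makes CPU
  training practical.
* The parameter-recovery experiment targets *realizable* kernels
  (generated by the same map at independently drawn random angles).
  Under SST the $C$ values a circuit emits are an affine map of a
  probability vector summing to one, so every realizable kernel slice
  has entry-sum $\frac{\pi}{2}(1 - C/2)$; an i.i.d. random target
  violates that constraint almost surely and would be unfittable by any
  angle setting.
* ReLU uses the convention of zero derivative at exactly zero;
  max-pooling breaks ties toward the first window position.  Gradient
  tests therefore probe configurations with no pre-activation at a
  kink, where one-sided conventions and central differences genuinely
  differ.
* Problem sizes used by the checks: circuits at $N \le 4$, $K \le 3$
  against dense-matrix oracles; layer oracles at channel counts
  $\le 8$; training smoke runs at 32×32 with 200 samples, 20 epochs,
  5 seeds.
* Batch-norm running statistics are model state (momentum 0.1), used at
  evaluation; training-mode forward uses batch statistics.
* QPG-managed layers carry no bias term (the published bias-free
  accounting: 576 classical parameters for a 64→1 3×3 layer); BN's
  shift plays that role in the miniature.
* Attention and linear layers, multi-class segmentation, pruning or
  distillation baselines, and real-CT ingestion beyond a NIfTI adapter
  stub are out of scope.
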