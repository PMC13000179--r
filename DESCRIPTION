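Package: qpgnet
Title: Hybrid Quantum-Classical Training of Convolutional Segmentation
    Networks via Quantum Parameter Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains convolutional neural networks for binary medical image
    segmentation in a hybrid quantum-classical fashion: the weights of
    selected convolution layers are not trained directly but generated by
    per-channel variational quantum circuits (QPGConv / QPGAConv), whose
    rotation angles are the trainable parameters.  Includes an exact
    statevector simulator for the shallow strongly-entangled ansatz, three
    post-processing strategies mapping quantum amplitudes or probabilities
    to weight values (real-component extraction, linear probability
    projection, shift-and-scale), low-rank adaptation baselines with
    matched parameter accounting, a miniature UNext-style encoder-decoder
    whose components can each be switched to quantum-generated training,
    sample-wise IoU/DSC evaluation, and a deterministic synthetic
    organ/tumor segmentation dataset generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
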