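Package: gammanet
Title: Gamma-Function Convolutional Decoding of EMG from Neural Envelopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal temporal convolutional decoders whose shared layers are
    closed-form Gamma-function kernels, differentiable in area, rate and onset
    delay, for reconstructing electromyogram (EMG) envelopes from multi-channel
    corticospinal multi-unit activity. Implements the preprocessing chain
    (zero-phase Butterworth filtering, Gaussian RMS envelopes, downsampling),
    session-dependent pointwise feature layers with a shared Gamma-kernel
    regression stack, full-batch ADAM training with early-stop checkpointing,
    a deterministic two-fold restart cross-validation protocol, pointwise
    linear and time-permutation controls, and a synthetic session generator
    with planted ground truth for end-to-end parameter-recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
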