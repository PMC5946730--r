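Package: neurofield
Title: Neural-Field Circuit Modelling of Cortical Cell-Class Size Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how locomotion and stimulus size shape the
    interactions among four cortical cell classes (Pyr, Pvalb, Sst, Vip) in
    mouse primary visual cortex.  The package covers the full analysis chain:
    synthesis of calcium-imaging sessions from a known ground-truth circuit,
    neuropil correction and dF/F0 preprocessing, skewness-based putative-Pyr
    classification, locomotion and size-tuning statistics (circular-shift
    shuffle tests, robust depth regression, modulation indices, erf-difference
    tuning fits, size-tuning-by-offset maps), Pyr-interneuron population
    coupling (spontaneous, signal and noise correlations, coupling angles,
    Watson's U2 permutation test), and a recurrent neural-field circuit model
    with ratio-of-Gaussians thalamic drive, Gaussian retinotopic kernels and
    threshold-linear subtractive/divisive inhibition, fitted by clamped-rate
    regression with an exhaustive kernel-width search and L0-penalized
    selection of locomotion-modulated weights.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm,
    pracma,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
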