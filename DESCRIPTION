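Package: lltherm
Title: Interleaved Look-Locker T1 Mapping and T1-Based Thermometry at Low Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, reconstruction and thermometry toolkit for
    interleaved Look-Locker partial-saturation-recovery T1 mapping with
    variable signal averaging, aimed at low-field (0.1 T) quantitative MRI.
    Provides the closed-form apparent-relaxation signal model and its
    inversions, variable-averaging schedule construction and SNR
    prediction, a digital vial-phantom k-space simulator with Gaussian
    phase-encode undersampling and Rician magnitude noise, the matching
    reconstruction chain (Hamming apodization, zero-filling, averaging
    normalization, background subtraction, region-growing segmentation,
    bounded pixel-wise T1* fitting, B1-corrected T1 conversion), linear
    T1-temperature calibration with a global sensitivity coefficient, and
    the statistical validation tools used to evaluate T1- and
    temperature-map quality.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite,
    car
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
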