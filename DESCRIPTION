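Package: EDXUnmix
Title: Unsupervised Spectral Mixture Analysis for Large-Scale
    Hyperspectral EDX Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the unsupervised analysis of hyperspectral
    energy-dispersive X-ray (EDX) spectrum images acquired during
    scanning transmission electron microscopy of biological tissue.
    Provides spatio-spectral preprocessing (channel trimming, binning,
    mean-kernel denoising), manifold-embedding-driven endmember
    extraction from 2D histograms of pixel embeddings, per-pixel
    non-negative least squares unmixing with globally scaled abundance
    visualisation, frame-accumulation convergence statistics, and
    abundance-driven point-prompt generation for promptable
    segmentation with a pluggable segmenter. A synthetic-phantom
    generator (characteristic X-ray lines plus Bremsstrahlung-like
    continuum under Poisson counting noise) supplies ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    pracma,
    MASS,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
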