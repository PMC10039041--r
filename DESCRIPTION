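Package: sersmil
Title: Multiple-Instance Deep Learning Diagnostics for Exosome SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation, preprocessing and classification of surface-enhanced
    Raman spectroscopy (SERS) spectra of plasma exosomes for multi-cancer
    liquid-biopsy screening. Provides a seeded synthetic cohort generator
    (Lorentzian peak signatures, smooth baselines, cosmic-ray spikes,
    low-signal anomalies, partial witness rates within sample bags), Raman
    signal conditioning (modified-z despiking, asymmetric penalized
    least-squares baseline correction, Savitzky-Golay denoising, band-intensity
    quality-control filtering), a multiple-instance-learning cancer-presence
    classifier built on a one-dimensional convolutional network with bag-mean
    aggregation, a one-vs-rest tissue-of-origin ensemble with a multi-layer
    perceptron integrator, ROC/PRC evaluation with bootstrap confidence
    intervals and fixed-operating-point metrics, and a seeded end-to-end
    experiment runner with learning-curve and ablation sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
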