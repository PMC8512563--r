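Package: carotidprint
Title: Biometric Identification from Carotid Artery Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for subject identification from carotid
    auscultation audio: synthetic carotid sound simulation with ground-truth
    cardiac states, signal quality screening, continuous wavelet transform
    spectra with generalized Morse wavelets, duration-dependent (hidden
    semi-Markov) segmentation of S1/systole/S2/diastole episodes, per-cycle
    spectral fingerprints, and a small convolutional neural network evaluated
    under stratified repeated k-fold cross-validation with per-class
    sensitivity, specificity, precision, F1 and accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
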