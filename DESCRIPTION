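Package: moca
Title: Multi-Omics Correlation Analysis for Sulfur-Fumigation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discriminate sulfur-fumigated from untreated botanical
    material by correlating near-infrared (NIR) spectroscopy with liquid
    chromatography-mass spectrometry (LC-MS) feature data. Provides a
    spectral preprocessing bank (MSC, SNV, detrending, vector normalisation,
    wavelet denoising, Savitzky-Golay smoothing and derivatives), PLS-DA
    chemometrics with Kennard-Stone splitting, cross-validation, VIP scores,
    S-plots, permutation testing and CV-ANOVA, synergy-interval PLS (SiPLS)
    waveband selection, generalized two-dimensional correlation spectroscopy
    (2D-COS), exact-mass sulfate/sulfite adduct screening with fine-isotope
    (34S vs 13C2/18O) diagnostics, MS/MS neutral-loss ladder annotation, and
    a synthetic-data generator emulating paired fumigated/untreated sample
    sets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
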