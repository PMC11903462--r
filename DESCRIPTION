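Package: eegnda
Title: Noise Data Augmentation Analysis for Multi-Label EEG Event Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how "natural" noise augmentation (longer input
    windows with offset-shifted labels) and synthetic Gaussian noise
    augmentation affect multi-label classification of hand-action events from
    multi-channel EEG. Includes a synthetic generator of grasp-and-lift style
    recordings with six overlapping trigger channels, a reader/writer for the
    Kaggle grasp-and-lift CSV dialect, random window extraction with
    offset-based labeling, a compact convolutional network trained with
    single-epoch checkpointing, micro/macro ROC-AUC sweeps over window length,
    LOWESS smoothing and steady-region summaries, and from-scratch detrended
    fluctuation analysis with banded Hurst-exponent fits validated against an
    exact fractional Gaussian noise synthesizer.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
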