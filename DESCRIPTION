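Package: emgregion
Title: Forearm-Region Analysis Pipeline for High-Density Surface EMG
    Gesture Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how electrode placement along the forearm
    affects hand-gesture classification from high-density surface
    electromyography (HD-sEMG). Provides a synthetic HD-sEMG generator
    emulating a 256-channel four-array montage with region- and
    gesture-dependent muscle activation, powerline interference, baseline
    drift and corrupted channels; Butterworth band-pass and harmonic notch
    filtering with overlapping window segmentation; eight per-channel
    time- and frequency-domain features (RMS, SSC, MYOP, skewness, WAMP,
    kurtosis, MNF, MDF); spatial outlier detection and reconstruction on
    electrode-grid feature maps; z-score normalization and
    variance-constrained PCA; one-vs-all linear SVM classification with
    grid search; intra-subject, inter-day and inter-subject validation
    protocols with movement-level leakage control; and nonparametric
    region comparison via Friedman and Wilcoxon signed-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
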