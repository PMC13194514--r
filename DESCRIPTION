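Package: mceegnet
Title: Multi-Cue EEG Networks for Depression Classification and PHQ-9 Severity Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multi-cue convolutional network for EEG-based
    depression assessment. Event-related potentials elicited by happy, fear
    and sad emotional cues are processed by three parallel EEGNet-style
    branches (temporal, depthwise-spatial and separable convolutions) whose
    features are fused to jointly classify depression versus control and to
    regress PHQ-9 severity with min-max label normalisation. Includes the
    ERP preprocessing pipeline (average reference, zero-phase Butterworth
    band-pass, cue-locked epoching, baseline correction, pluggable artifact
    rejection), leave-one-subject-out cross-validation with fold-local label
    normalisation, the full classification and regression metric suite
    (including Cohen's kappa), a synthetic cue-locked ERP cohort generator
    with severity-dependent component amplitudes over 1/f plus white noise,
    and HDF5 / EEGLAB epoch I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    rhdf5,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
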