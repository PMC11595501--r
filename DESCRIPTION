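Package: topodecode
Title: Imagined-Speech Decoding from Sequences of EEG Topographic Maps
Version: 0.1.0
Authors@R:
    person("Topodecode", "Maintainers", email = "maintainers@topodecode.org",
           role = c("aut", "cre"))
Description: Transforms multichannel EEG trials into sequences of topographic
    scalp images and classifies imagined words with hybrid three-dimensional
    convolutional plus recurrent neural networks (3DCNN-LSTM, 3DCNN-StackLSTM,
    3DCNN-BiLSTM). Provides a standard 10-20/10-10 spherical electrode montage
    with azimuthal-equidistant head projection, inverse-distance-weighted scalp
    interpolation, class-balanced stratified train/test splitting, a synthetic
    imagined-speech EEG generator for offline testing, and subject-dependent
    training and evaluation with per-subject and cross-subject average
    accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
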