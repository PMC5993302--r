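Package: sleepstates
Title: Unsupervised Discovery of Sleep Substages from EEG/EMG Epoch Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers latent sleep/wake substages in rodent EEG/EMG
    recordings with a mean-covariance restricted Boltzmann machine (mcRBM)
    trained on per-epoch spectral band ratios and EMG tone. Provides epoch
    segmentation and band-power extraction from EDF recordings, model
    training and deterministic encoding of epochs into binary latent states,
    information-theoretic evaluation of the states against manual W/NR/R
    scoring, Markov transition graphs with force-directed layouts, circadian
    occupancy profiles with polynomial peak detection, group discrimination
    by leave-one-subject-out ensemble classification, sleep-deprivation
    rebound quantification, and a fully seeded synthetic cohort generator
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    igraph,
    xml2,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
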