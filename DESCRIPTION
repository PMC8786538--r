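Package: ocuclean
Title: Detection and Mitigation of Ocular Artifacts in Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase removal of eye-blink (EOG) contamination from
    multichannel EEG epochs. The detection phase decomposes each epoch with a
    five-level four-band wavelet filter cascade and Pisarenko harmonic
    analysis, extracts concatenated PCA and ICA features, and classifies
    epochs with a one-dimensional deformable convolutional network whose epoch
    count and learning rate are tuned by a distance-sorted Electric Fish
    Optimization (DS-EFO) metaheuristic. The mitigation phase splits detected
    artifactual epochs with Empirical Mean Curve Decomposition (EMCD),
    denoises the artifact-bearing component with a deformable network, and
    reconstructs the cleaned signal by inverse EMCD. Includes a seeded
    semisimulation module that generates clean EEG, blink-like EOG
    contaminants and labelled contaminated datasets for quantitative
    evaluation, plus a full evaluation-metric suite and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
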