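Package: usvdyad
Title: Sex Differences in Mouse Ultrasonic Vocalizations from Microphone-Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of ultrasonic vocalizations (USVs) recorded
    from freely interacting male-female mouse pairs with an 8-channel
    microphone array. Detects vocal signals as connected time-frequency
    regions using multitaper spectral estimates and Thomson's harmonic
    F-test, localizes each signal by leave-one-microphone-out jackknifing of
    time-difference-of-arrival estimates, assigns signals to individual mice
    through a mouse probability index, quantifies seven acoustic features
    per signal, classifies following/followed/not-close behavioral contexts
    from video trajectories, and compares the sexes with Mann-Whitney tests
    and a Monte-Carlo median-difference index. A synthetic-data module
    generates ground-truth-labelled trajectories, chirp waveforms, array
    audio and feature tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
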