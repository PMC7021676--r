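Package: squeaktrace
Title: Attribution of Mouse Ultrasonic Vocalizations and Behavioral
    Response Statistics for Dyadic Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying ultrasonic vocal communication in freely
    interacting pairs of mice. Provides a synthetic-data generator for
    dyadic recordings with known ground truth (correlated random-walk
    tracks, distance-dependent vocal emission, eight-channel audio
    rendering), multitaper harmonic F-test segmentation of 30-110 kHz
    vocal signals, leave-one-microphone-out (jackknife) sound-source
    localization with a Mouse Probability Index for assigning each signal
    to a vocalizer, proximity and vocal-timing descriptors, and the
    speed-matched vocal versus non-vocal trajectory statistic for
    quantifying receiver acceleration after vocal emission, including
    subsampling null distributions and epoch-resolved analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
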