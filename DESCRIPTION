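Package: sealscape
Title: Underwater Pinniped Vocal Repertoire and Soundscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for passive acoustic monitoring of pinniped vocal
    repertoires and their sonic environment. Provides category-specific
    acoustic feature extraction (duration, fundamental frequency, frequency
    excursion, spectral peak, energy quartiles, pulse rate) from labelled
    call segments, Random-Forest out-of-bag validation of an aural-visual
    call-type classification with confusion-matrix summaries and Gini
    variable importance, calibrated soundscape metrics (long-term
    spectrogram averages, power-spectral-density percentiles, broadband and
    octave-band levels), and hourly/daily vessel-noise presence budgets.
    Includes a synthetic-data generator that emulates an 18-type monk-seal
    call repertoire over snapping-shrimp, vessel and flow noise, so the
    whole pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
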