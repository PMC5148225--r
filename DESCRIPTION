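Package: predecode
Title: Predictive Ensemble Decoding Models of Auditory Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, inference and learning for a Bayesian predictive
    ensemble decoding model of auditory neurons. Sounds are modelled as
    independently switching nonnegative spectral features driving Poisson
    receptor responses; feature detectors perform online mean-field filtering
    with divisive explaining-away, and their predictive fields can be learned
    by online expectation-maximization. Includes ridge-regularized normalized
    reverse correlation estimators for encoding (STRF/SRF) and decoding
    filters, stimulus reconstruction, transient/sustained response analysis,
    and a synthetic-data generator emulating speech-like spectrograms so the
    full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
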