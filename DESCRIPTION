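Package: oscitrack
Title: Information-Theoretic Analysis of Speech-Envelope Tracking by Brain Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies how quasi-rhythmic components of the speech amplitude
    envelope entrain cortical oscillations at multiple time scales. Provides a
    cochlear-spaced filterbank wideband envelope, band-limited instantaneous
    phase and amplitude, binned mutual information with quadratic-extrapolation
    bias correction, phase-locking values, cross-frequency phase-amplitude
    comodulograms, acoustic edge detection with edge-locked phase-reset and
    phase-coding analyses, lateralisation and randomisation group statistics,
    and a synthetic-data generator with known ground-truth couplings for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
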