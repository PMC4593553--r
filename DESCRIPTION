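Package: labelkin
Title: Kinetic Modeling and Normalization of Stable-Isotope Cell-Labeling Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating cell proliferation and disappearance rates
    from deuterium labeling experiments (deuterated water and deuterated
    glucose). Provides precursor-availability forcing functions (body-water
    enrichment curves, square glucose pulses, diurnally modulated pulses),
    closed-form solutions of the standard labeling models (kinetic
    heterogeneity, multi-exponential, growing culture, bone-marrow delay,
    delayed observation, water-forced granulocyte), a raw-pool numerical
    oracle for verification, three normalization schemes (conventional
    glucose, reference-population plateau, fitted water scaling factor),
    multi-start bounded nonlinear least-squares fitting with AICc order
    selection, Akaike-weight model averaging and bootstrap confidence
    intervals, seeded synthetic-study generators for in vitro, murine and
    human designs, and an end-to-end normalization-reconciliation analysis.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
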