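Package: polypwatch
Title: Time-Lapse Quantification and Permutational Statistics for Coral
    Polyp Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for polyp-expansion behaviour
    of passive suspension feeders observed by time-lapse imaging. Generates
    synthetic colony video with known aperture dynamics, segments frames
    into open-polyp, coenenchyme and background classes, labels and tracks
    polyp regions, derives open-surface-area and frame-differencing
    activity series, detects endogenous rhythms with the Lomb periodogram
    and analytic peak significance, and applies distance-based
    permutational statistics (one-way, nested and crossed PERMANOVA,
    pairwise Monte-Carlo tests, SIMPER) to field-survey and
    flume-experiment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    png,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
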