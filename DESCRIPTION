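Package: bullseye
Title: Stochastic Modelling and Measurement of Petal Bullseye Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the pigmented/unpigmented boundary of a petal
    bullseye pattern keeps its relative position while the petal grows.
    Implements a one-dimensional stochastic simulator of a two-fate cell array
    (fate-dependent logistic cell expansion and tissue-length-gated cell
    division), observables and ratio-grid parameter scans over expansion and
    division rates, exponential rate estimation from staged cell counts and
    lengths, a measurement pipeline for segmented-cell tables (window-averaged
    cell-area boundary detection with Savitzky-Golay smoothing, EdU nucleus
    density profiles, region summaries), seeded synthetic-data generators for
    every input table, and preference/learning analyses for pollinator choice
    experiments with bullseye-patterned artificial flowers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
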