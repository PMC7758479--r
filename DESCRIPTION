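Package: dcaa
Title: Lagged Co-Regulation Mining of Time-Series Phosphoproteomic Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers candidate protein-protein interactions from
    time-series phosphoproteomic profiles. Peptide time courses are
    partitioned by shape similarity (full-trend, segment-angle, or Pearson
    clustering), class representatives are compared through delayed sliding
    windows to capture the lag between upstream and downstream signalling
    events, co-moving classes are collected into shopping-basket records
    and mined with the Apriori algorithm, and the resulting association
    rules are expanded into protein pairs by one-, two- and three-step
    reasoning. Predictions are scored against a reference interaction set
    with a seeded random-matching baseline and an empirical significance
    test. Includes a seeded synthetic-data generator with planted lagged
    influences for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
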