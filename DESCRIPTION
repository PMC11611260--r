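Package: cytosets
Title: Learned Set-Level Aggregation of Single-Cell Morphological Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Aggregates single-cell morphological feature tables (one row per
    segmented cell, CellProfiler-style columns) into well-level profiles with a
    permutation-invariant Deep Sets network trained by supervised contrastive
    learning, and evaluates profiles by cosine-similarity retrieval (replicate
    and mechanism-of-action mean average precision). Includes the classical
    average-profiling baseline with RobustMAD normalization and feature
    selection, per-cell relevance scoring (sensitivity analysis and
    critical-point analysis) for model interpretation, and a synthetic-data
    generator producing plates of replicate wells whose classes differ in
    means, covariances, or skewness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
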