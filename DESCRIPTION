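Package: styletree
Title: Behavioral Style Taxonomies from Visual Search and Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive perceptual taxonomies of artistic styles from
    behavioral data. Implements the singleton-search pipeline (fast-guess
    exclusion, winsorization, accuracy and reaction-time matrices, the
    effective reaction-time statistic, inverse-distance conversion,
    asymmetry relations, average-linkage clustering) and the eye-tracking
    pipeline (fixation binning into spatial grids, normalization, grand-bias
    subtraction, per-image Pearson correlation of gaze heatmaps, averaging
    across images, clustering), together with a synthetic behavioral-data
    generator that plants a known style taxonomy so that both pipelines'
    ability to recover it can be verified without human data. Trees are
    exchanged as newick; tabular data as delimited text.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
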