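Package: vamrscreen
Title: Behavioral Fingerprinting and Effect-Directed Chemical Analysis for
    Larval Zebrafish Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for effect-directed analysis of complex environmental
    mixtures with the larval zebrafish visual and acoustic motor response
    (VAMR) assay. Extracts 26 behavioral endpoints from per-larva locomotor
    activity traces under a configurable stimulus schedule, computes strictly
    standardized mean difference (SSMD) effect sizes with bootstrap tests and
    Benjamini-Hochberg adjustment, clusters treatment fingerprints against a
    reference library of neuroactive compounds to generate mode-of-action
    hypotheses, and refines tentative GCxGC-MS identifications by retention
    binning, van den Dool-Kratz retention indices, partial least-squares
    retention prediction from physicochemical descriptors, and deviation-based
    plausibility filtering. Includes mixture and loading arithmetic and
    synthetic-data generators for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    igraph,
    ape,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
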