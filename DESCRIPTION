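Package: coexnet
Title: Signed Weighted Gene Coexpression Networks with Module-Trait
    Statistics and Cross-Disease Comparison
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds signed weighted gene coexpression networks from bulk
    expression matrices (soft-threshold adjacency, topological overlap,
    average-linkage clustering with tree-based branch cutting), summarizes
    modules by eigengenes, relates modules to continuous clinical traits and
    sample groups, quantifies cross-dataset module preservation, performs
    EASE-style (jackknifed Fisher) gene-set enrichment, and compares
    impairment-correlated transcription between two diseases via quadrant
    classification of paired per-gene trait correlations. Ships a synthetic
    data generator with planted module and trait structure for end-to-end
    validation, and a plain-text-configured pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
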