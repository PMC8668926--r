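Package: limbscape
Title: Single-Cell Expression Classes, Cluster Composition Tests and
    Capture-HiC Post-Processing for Enhancer-Deletion Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to dissect how the loss of a single enhancer reshapes a
    developmental gene's expression across limb-bud cell populations.
    Implements three-class (non/low, intermediate, high) expression calling
    of single cells from kernel-density intersection thresholds, per-cluster
    class-proportion and fold-change accounting, a permutation-based
    differential proportion analysis of cluster composition, and
    post-processing of capture Hi-C contact data (Knight-Ruiz matrix
    balancing, per-subdiagonal joint scaling, subtraction maps, percentile
    truncation, and virtual-4C profile extraction with bedGraph export),
    together with small bulk RPKM/z-score/log2 fold-change utilities.
    Seeded synthetic-data generators emulate the cluster-structured cell
    populations and distance-decaying contact maps that the pipeline
    consumes, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
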