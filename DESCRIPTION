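Package: dyeswapr
Title: Dye-Swap Analysis of Two-Color Spotted Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of two-color spotted-microarray depletion
    experiments with dye-swapped technical replicates: spot quality control,
    orientation-corrected log-ratio computation, median normalization,
    duplicate-spot and replicate combining, fold-change differential-expression
    calling, classification of the stress-response dependence of each gene on a
    depleted factor (weakly/strongly/totally dependent), hypergeometric
    gene-set and transcription-factor enrichment, published-list overlap and
    regression statistics, and complete-linkage hierarchical clustering under
    uncentered correlation with TreeView-compatible output.  A synthetic-data
    generator emulates dye-swapped two-channel arrays with planted fold-change
    and dependence-class structure so every stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
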