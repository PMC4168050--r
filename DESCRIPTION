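Package: nodentropy
Title: Tissue-Specificity and Spatio-Temporal Analysis of Nodule Gene Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines microarray expression compendia of the legume Medicago
    truncatula for nodule-specific gene families such as the
    nodule-specific cysteine-rich (NCR) peptides. Aggregates experimental
    conditions into tissue classes, quantifies tissue specificity by the
    Shannon entropy of relative expression profiles, classifies genes into
    temporal activation waves over the nodule developmental time course,
    profiles expression along the nodule zonation axis, runs differential
    screens (senescence induction, nodule zones, infected versus
    uninfected cells), computes expression-strength statistics, and flags
    cross-contaminated samples with bacterial marker genes. Ships a
    synthetic compendium generator with planted ground truth so every
    stage of the analysis is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse,
    pheatmap,
    withr
Config/testthat/edition: 3
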