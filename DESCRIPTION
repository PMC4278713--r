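Package: gbmsub
Type: Package
Title: Immunohistochemistry and FISH Based Molecular Subclassification of Glioblastoma
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assigning molecular subclasses (Proneural, Classical,
    Mesenchymal) to newly diagnosed glioblastomas from routine pathology
    readouts. Implements semi-quantitative per-core immunohistochemistry
    scoring and aggregation across tissue-microarray cores, EGFR/CEP7 FISH
    amplification calling, Kendall tau-b average-linkage biclustering of the
    standardized score matrix with sequential marker pruning, the recoded
    PN/MES index with strict +/-1 thresholds, an ordered three-step
    rule-based subclass assignment scheme, and a qRT-PCR delta-Ct metagene
    score for transcriptional corroboration. Ships deterministic worked
    fixtures built from published cohort marginals and a configurable
    synthetic-cohort generator so every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
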