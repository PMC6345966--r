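Package: altimiR
Title: Small RNA Profiling of Plant Populations Along Altitudinal Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing toolkit for comparing miRNA
    expression between natural plant populations. Implements hierarchical
    read classification against contaminant RNA pools, miRNA quantification
    with reads-per-million normalization, pairwise differential expression by
    Pearson chi-square on 2x2 contingency tables, a seven-class isomiR
    taxonomy with 3' non-templated addition analysis, 5p/3p arm-usage
    statistics, structural validation of candidate miRNA hairpins against
    duplex criteria, principal-component analysis of bioclimatic variables
    with expression correlation, and a fully seeded synthetic-data generator
    that emulates a multi-population field/glasshouse study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    ape,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, DifferentialExpression, Preprocessing
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
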