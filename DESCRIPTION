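Package: episig
Title: DNA Methylation Episignatures and Phenotypic Screen Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and validation of DNA methylation episignatures from
    beta-value arrays (reference-based blood cell deconvolution, age-CpG
    screening, per-CpG linear models with empirical-Bayes variance
    moderation, PCA and hierarchical-clustering validation), a
    genotype-by-treatment interaction caller for drug-corrected methylation
    sites, overdispersion-corrected count-based differential methylation
    with CpG-to-gene annotation and expression overlap, and rank-based
    statistics for ordinal phenotypic screens. Includes a synthetic-data
    module that generates array, bisulfite-count, ordinal-score and
    gene-list datasets with known planted structure so every stage can be
    tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    pracma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
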