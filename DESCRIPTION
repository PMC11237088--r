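Package: scVarLink
Title: Linking Genetic Variants to Cell-Type Expression and Traits in
    Single-Nucleus RNA-Seq Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested statistical chain for single-nucleus RNA-seq cohorts
    with paired genotypes: cell-level quality control including a
    sigmoid-inflection UMI cutoff, per-cell-type pseudobulk cis-eQTL mapping
    with conditional false discovery rate control, approximate-Bayes-factor
    colocalization of two association tracks, a four-condition causal
    inference test for (locus, mediator, trait) trios with permutation FDR,
    multiscale kNN differential-abundance detection between two conditions,
    and donor-level permutation trait enrichment. Ships synthetic-data
    generators with planted effects so the whole chain is testable without
    any cohort download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    glmnet,
    igraph,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, SNP, GeneExpression,
    DifferentialExpression, GenomeWideAssociation
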