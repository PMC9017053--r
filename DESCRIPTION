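Package: genemotif
Title: Gene-Motif Based Subtyping of Cancer Somatic Mutation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cancer subtypes from somatic point mutations using
    compound "gene-motif" features that pair a mutated gene with the
    trinucleotide substitution class (one of the 96 strand-collapsed SBS
    classes) of the mutation. Provides a statistical pipeline that selects
    significantly mutated genes with a pooled negative-binomial background
    and significantly mutated gene-motifs with a pooled beta-binomial
    background (distribution choice assisted by Cullen-Frey diagnostics and
    the Cramer-von Mises statistic), recursive Gaussian-mixture model-based
    clustering of samples on the significant gene-motif matrix with a
    minimum-cluster-size rule and outlier merge-back, subtype
    characterization (Fisher's exact subtype-vs-rest scans, motif
    preferences, consequence-type tables, mutational load, transcript
    enrichment, hypergeometric over-representation), mutational-signature
    extraction by non-negative matrix factorization with stability-based
    selection of the signature count, Kaplan-Meier/log-rank survival
    comparison across subtypes, and a seeded synthetic-cohort generator
    with planted subtype structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    MASS,
    mclust,
    survival,
    jsonlite,
    withr,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
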