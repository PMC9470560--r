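Package: cfScope
Title: Genome-Wide Cell-Free DNA Profiling for Immune-Mediated Disease
    Signatures in Shallow WGS
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of binned read-count profiles from shallow whole-genome
    sequencing of plasma cell-free DNA (cfDNA). Implements reference-set
    chromosomal z-scores, the trimmed genome-wide quality score (QS), and the
    conclusive/inconclusive call used in non-invasive prenatal screening
    (NIPS); unsupervised exploration of genome-wide profiles by principal
    component embedding, k-nearest-neighbour graphs with Walktrap community
    detection, tSNE layouts and Ward trees; supervised disease classification
    with class-weighted support vector machines evaluated by leave-one-out
    cross-validation at a fixed-specificity operating point; and cohort-level
    statistics (prevalence-based odds ratios, cluster enrichment, adjusted
    logit models). A negative-binomial synthetic-cohort generator with GC
    bias, fetal-fraction mixtures, trisomies, disease signatures, replicates
    and batch effects makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    e1071,
    Rtsne,
    pROC,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, CopyNumberVariation, Coverage, Classification,
    Clustering, PrincipalComponent, ImmunoOncology
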