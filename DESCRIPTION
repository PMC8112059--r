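Package: StarrCRE
Title: Locus-Level Analysis of Androgen-Receptor Enhancer Activity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locus-level functional annotation of androgen receptor
    (AR) cis-regulatory elements. Implements three-class enhancer calling
    (inducible, constitutive, inactive) from STARR-seq count matrices with a
    negative-binomial Wald test, interaction-frequency statistics and
    centrality analysis over chromatin-loop derived CRE networks, DeltaCon
    affinity-matrix comparison of condition-specific co-accessibility graphs
    with per-node impact scores, SES-normalized sigmoid occupancy features,
    and a bagged L1-regularized multinomial logistic classifier with binding
    energy ranking of DNA-binding factors. A synthetic-data module generates
    all pipeline inputs with planted structure so every stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    DESeq2
Config/testthat/edition: 3
biocViews: FunctionalGenomics, GeneRegulation, Epigenetics, Network,
    Classification, Sequencing
RoxygenNote: 7.3.3
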