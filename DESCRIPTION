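Package: cernet
Title: Competing Endogenous RNA Network Inference from circRNA, miRNA and
    mRNA Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-alignment analysis pipeline for joint circRNA, miRNA and
    mRNA expression studies of brain injury: back-splice-junction catalogue
    construction by dual-caller intersection and junction-read filtering,
    TPM/FPKM normalization, negative-binomial Wald differential expression
    with Benjamini-Hochberg correction, miRNA seed-match target-site
    prediction, competing-endogenous-RNA (ceRNA) triplet assembly with
    Pearson-correlation hub selection, and hierarchical-clustering / PCA
    discrimination of expression signatures. Includes a fully parameterised
    synthetic-data generator with known ground truth (planted differential
    expression, sponge triplets, circRNA classes) so that every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
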