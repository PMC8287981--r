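Package: cafpaths
Title: Classification and Developmental Path Inference for Cancer-Associated
    Fibroblast Subpopulations in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A multi-stage analysis pipeline for single-cell RNA-seq of
    tumour and matched normal tissue that identifies fibroblasts with a
    strict two-step marker screen, clusters them per sample by k-means with
    the number of clusters chosen from the sum-of-squared-error curve,
    classifies clusters into a fibroblast taxonomy (perpetually activated
    CAFs and their inflammatory and myofibroblastic subtypes in tumours;
    tissue-resident MSC-like and resting fibroblasts in normal tissue),
    traces each tumour cluster's putative normal-tissue origin by pairwise
    Spearman correlation of cluster centroids, and orders cells along a
    differentiation axis with a principal-curve pseudotime rooted at the
    MSC-like population. A negative-binomial simulator generates mixed-tissue
    datasets with planted subpopulations, marker programs and a latent
    differentiation continuum, so every stage is verifiable against ground
    truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
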