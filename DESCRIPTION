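Package: crossmark
Title: Cross-Context Enhancer Prediction from Histone-Mark Peak Overlaps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates how well enhancer-associated histone modifications
    (H3K4me1, H3K27ac) assayed in one cellular context predict regulatory
    enhancers active in a different developmental stage, tissue, or species.
    Regions and ChIP-seq peak calls are represented as GRanges; binary
    presence/absence overlap features feed a fixed suite of six supervised
    classifiers evaluated by stratified five-fold cross-validation with
    fold-averaged ROC curves, normalized Gini feature importance, and
    Fisher's exact enrichment statistics. Includes a chromosome- and
    length-matched background sampler and a synthetic epigenome generator
    that emulates developmental-proximity decay of mark informativeness,
    tissue-shared ubiquitous elements, and cross-species coordinate
    degradation, so the full analysis grid runs end-to-end without external
    downloads.
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
    GenomeInfoDb,
    SummarizedExperiment,
    ranger,
    e1071,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, FunctionalGenomics, Classification, ChIPSeq,
    GeneRegulation
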