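Package: glycanShap
Title: Predicting and Explaining Single-Cell Glycan Phenotypes from
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts a binarized cell-surface glycan phenotype (lectin-seq
    PHA-L signal, a proxy for beta-1,6-branched N-glycans) from single-cell
    transcriptomes and explains the prediction. Provides a synthetic paired
    transcriptome+lectin data generator with planted driver genes, centered
    log-ratio normalization and quartile label construction, a feed-forward
    neural network classifier with ensemble baselines, Shapley-value feature
    attribution via multi-reference DeepLIFT-style backpropagation with
    sampling and exhaustive oracles, permutation feature importance, Wilcoxon
    rank-sum differential expression with FDR control, and an end-to-end
    pipeline with ground-truth recovery reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    withr,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
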