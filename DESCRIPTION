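Package: plncHDeep
Title: Hybrid Deep Learning Prediction of Plant Long Noncoding RNAs from
    Two Sequence Encodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies plant transcripts as long noncoding RNA (lncRNA) or
    messenger RNA (mRNA) from the raw nucleotide sequence alone. Sequences
    are encoded two ways: as p-nucleotide token vectors feeding a
    bidirectional LSTM, and as one-hot 4xN matrices feeding a small
    convolutional network. The two models' confidence probabilities are
    fused at decision level by one of three explicit hybrid strategies
    (greedy, CNN-dominant, LSTM-dominant). Also provides the surrounding
    protocol: k-means-based undersampling of the majority class, a
    90-dimensional classical feature extractor (k-mer frequencies, open
    reading frame features, secondary-structure features), stratified
    splits and 5-fold cross-validation, threshold metrics, ROC/AUC, and
    Fisher's least-significant-difference test, plus a synthetic transcript
    generator with controllable class separability for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
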