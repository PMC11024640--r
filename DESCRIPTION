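Package: plantlnc
Title: Trainable Coding-Potential Classifiers and an Annotation Pipeline
    for Plant Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification and characterization of plant long non-coding
    RNAs (lncRNAs) from assembled transcripts. Implements retrainable
    coding-potential classifiers over three feature schemas (ORF/Fickett/
    hexamer-bias logistic regression, k-mer profile SVM, and a
    composition/spectrum SVM), a stringent two-model ensemble rule,
    evaluation metrics with ROC/AUC, and the downstream annotation stages:
    candidate filtering, protein-homology filtering, six-way positional
    classification against a reference annotation, transposable-element
    origin, and greedy redundancy removal. Ships seeded synthetic-data
    generators (mRNA-like and lncRNA-like transcripts, planted-truth toy
    genomes) so every stage is testable end to end without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    e1071,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
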