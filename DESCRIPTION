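Package: kmersvm
Title: Predictive Regulatory Sequence Vocabularies via Kmer Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns predictive DNA sequence vocabularies from genomic region
    sets (ChIP-seq or DNase-seq peaks). Builds negative interval sets matched
    to the positive set's length, GC and repeat-fraction profile by seeded
    rejection sampling on a prefix-sum genome index; maps sequences to
    strand-collapsed, unit-norm kmer count vectors (the spectrum and weighted
    spectrum kernels); trains a cost-weighted soft-margin linear SVM by dual
    coordinate descent and reports every kmer's weight; calibrates posterior
    probabilities from cross-validated scores by Platt scaling; evaluates
    classifiers with ROC and precision-recall curves; exports top-weighted
    kmers as MEME-format position weight matrices, scans sequences by maximum
    log-odds, and compares motifs by column-wise similarity. A seeded
    planted-motif generator provides synthetic benchmarks end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
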