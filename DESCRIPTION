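Package: bcrclassify
Title: Supervised Classification of B-Cell Receptor Repertoires from Normal and Tumor Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether B-cell receptor / immunoglobulin (BCR/Ig)
    heavy-chain repertoires sequenced from matched normal and tumor tissue carry
    tissue-distinguishing signal. Implements clonotype assignment (shared V/J
    gene, CDR3 length, small CDR3 nucleotide distance), extraction of
    tissue-specific dominant clones, Kidera-factor physicochemical encoding of
    CDR amino-acid sequences, four per-sequence classifiers (patient-averaged
    naive Bayes on V/J usage and on CDR lengths, a linear support-vector
    classifier on somatic-hypermutation counts, and a 1-D convolutional network
    or kernel/forest alternative on encoded CDRs), a boosted linear ensemble of
    their probabilities, tissue-level aggregation of per-sequence scores, and
    evaluation machinery (patient-level nested cross-validation, ROC/AUC,
    within-patient permutation tests, paired signed-rank comparisons, CDR motif
    frequency matrices). A synthetic paired-repertoire generator with planted,
    per-channel effects supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
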