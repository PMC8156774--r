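Package: crisprlink
Title: Graph-Based Link Prediction of CRISPR/Cas9 sgRNA Off-Target Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts sgRNA off-target activity in the CRISPR/Cas9 system by
    casting it as link prediction on a sequence graph. Unique sgRNA and
    23-nt target-site sequences become nodes, experimentally confirmed
    off-target pairs become edges, and a graph convolutional network
    trained end-to-end with binary cross-entropy scores candidate links
    from sequence-intrinsic features (k-mer occurrence counts or
    positional one-hot encodings). Includes per-guide cluster
    undersampling for class imbalance, a random-walk/skip-gram embedding
    baseline with a logistic-regression link classifier, auROC
    evaluation, and a seeded synthetic data generator that emulates the
    cluster structure of curated off-target benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
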