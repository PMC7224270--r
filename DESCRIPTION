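Package: metl
Title: Multi-Source Ensemble Transfer Learning for Tabular Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-source ensemble transfer learning (METL) for tabular
    classification with few labeled target samples. Phase 1 selects
    transferable source instances by iterative unanimous agreement of three
    heterogeneous probabilistic classifiers (penalized softmax regression,
    a radial-kernel support vector machine with Platt-calibrated
    probabilities, and a single-hidden-layer neural network) and averages
    them into one classifier per source domain. Phase 2 weights the
    per-source classifiers by the mutual information between each sampled
    source and the labeled target data, normalized onto the simplex, and
    predicts from the weighted probability mixture. Includes a synthetic
    domain-shift generator, a K-means single-attribute domain splitter,
    SMOTE class balancing, equal-weight and target-only baselines, and a
    repeated-evaluation benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
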