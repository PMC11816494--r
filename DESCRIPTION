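Package: cubicpat
Title: Ordinal Channel-Triplet EEG Features with Explainable Selection and Ensemble kNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Explainable feature engineering for multichannel EEG classification.
    Extracts cubic-pattern features (histograms of base-n codes over descending
    channel-rank triplets at every time sample), selects discriminative features
    with cumulative-weighted iterative neighborhood component analysis (CWINCA),
    classifies with an ensemble kNN that sweeps 30 parameter configurations and
    adds 28 iterative-majority-vote combinations (tkNN), and decodes selected
    feature indices into Directed-Lobish cortical-lobe symbol sequences with
    transition tables, Shannon entropy, complexity ratios, and connectome graph
    export. Includes a subject-structured synthetic EEG generator and a
    reproducible pipeline runner with 10-fold and leave-one-subject-out
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
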