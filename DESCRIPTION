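Package: coilgram
Title: Coiled-Coil Domain Prediction with a Grammar-Constrained Hidden CRF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A trainable toolkit for predicting coiled-coil domains in
    protein sequences: per-residue heptad register scoring with a
    convolutional/bidirectional-LSTM network, grammar-constrained segment
    and register decoding with a hidden conditional random field and
    posterior-Viterbi decoding, and oligomerization-state classification
    from register-pooled residue embeddings.  Includes the full evaluation
    suite (residue and segment precision/recall/F1, segment-overlap SOV
    scores, precision-recall AUC, per-class Matthews correlation, and
    bootstrap significance testing) and a synthetic benchmark generator
    with planted heptad helices so every stage is trainable and verifiable
    offline.  Sequence encoding is a pluggable contract so precomputed
    protein language model embeddings can be dropped in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
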