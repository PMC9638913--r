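Package: ssmotif
Title: Interpretable Sequence-Structure Motif Regression for RNA-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the RNA sequence and secondary-structure specificity of
    RNA-binding proteins from in vitro selection data (SELEX-, RBNS- or
    CLIP-style bound/background probe sets). Probes are annotated under seven
    alphabets spanning primary sequence, secondary-structure context at three
    granularities, and their products; position frequency matrices enriched in
    the bound set are discovered per alphabet, scored by a top-four-window-sum
    scanner, and combined by L1-regularized logistic regression that is
    iteratively simplified to a small weighted motif set. The retained weights
    yield per-alphabet and paired-base structure-specificity metrics. A
    gap-aware hidden Markov model over discovered motifs captures variably
    spaced bipartite binding, and a seeded simulator generates SELEX-like
    probe pools with planted sequence, hairpin-embedded and bipartite motifs
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    glmnet,
    ggplot2,
    jsonlite,
    randomForest,
    generics,
    withr,
    stats,
    utils,
    Biostrings
Suggests:
    optparse,
    stringr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
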