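Package: foldlingo
Title: Bilingual Modeling of Protein Sequence and 3Di Structure Strings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for bilingual protein language modeling over
    amino-acid sequences and the 20-state 3Di structural alphabet. Provides a
    dual-alphabet character tokenizer with translation-direction prefixes and
    span-corruption sentinels, a seeded generator of a synthetic bilingual
    protein universe (paired AA/3Di sequences, pLDDT-like quality scores,
    clusters and a fold/superfamily/family hierarchy), dataset curation filters
    and cluster-aware splitting, a small trainable encoder-decoder translation
    model with the two-phase denoising-then-translation schedule, the full
    stochastic decoding stack (beams, temperature, nucleus, top-k, repetition
    penalty), a convolutional per-residue 3Di classification head with
    confidence thresholding, global Needleman-Wunsch alignment under a custom
    3Di substitution matrix with roundtrip-accuracy filtering, and
    remote-homology / embedding-based annotation-transfer benchmarks.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
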