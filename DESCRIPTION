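Package: ocsr
Title: Optical Chemical Structure Recognition with an Image-to-SELFIES Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for optical chemical structure recognition
    (OCSR): converting 2D bitmap depictions of single molecules into
    machine-readable structures. Provides rule-based curation of SMILES
    corpora, deterministic 2D depiction rendering with photometric
    augmentations, a robust SELFIES-style molecular string grammar with
    bracket tokenization and vocabulary construction, MaxMin (farthest-point)
    diversity splitting over fingerprint Tanimoto distance, a sharded binary
    dataset container, an image-captioning transformer (encoder-decoder
    attention) trained with Adam under a warmup learning-rate schedule, and
    evaluation of predicted structures by fingerprint Tanimoto similarity and
    InChI-based isomorphism. Standard chemistry operations (canonicalization,
    InChI generation, path fingerprints, 2D coordinates) are delegated to
    Open Babel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Open Babel (the 'obabel' executable on the PATH)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
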