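Package: dgcgrn
Title: Directed Graph Convolutional Inference of Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from expression data by
    link prediction with a directed graph convolutional network built on
    first- and second-order proximity matrices. Node features can be enriched
    with gene-sequence information (k-mer Bi-GRU hidden features and
    physicochemical descriptors: Z-curve endpoint, GC content, AT/GC ratio,
    nucleotide composition, adjacent dinucleotide frequencies) and with
    conditional-variational-autoencoder generated features that compensate for
    low-degree nodes. Training supports a dynamic edge-reweighting strategy,
    repeated k-fold cross-validation with negative sampling, and an ablation
    harness. Ships a synthetic benchmark generator (scale-free directed graph,
    sigmoidal expression model, composition-biased sequences) so the whole
    pipeline runs without external data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
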