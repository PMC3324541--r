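Package: ionrules
Title: Combinatorial Expression Rules for Binary Ion-Channel Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts combinatorial Boolean expression rules from binary
    single-cell ion-channel gene expression panels. Per target gene, an
    incremental support-vector-machine wrapper greedily selects other genes
    that improve cross-validated prediction on top of layer, morphology and
    electrical-type labels; per-type truth tables are minimized into AND/OR/NOT
    rules (exact Quine-McCluskey with don't-cares); model significance is
    assessed against random-input and Bernoulli-resampled null models; and the
    selected inputs are assembled into a directed gene-predictivity network.
    Includes a synthetic-data generator with planted rules and false-negative
    noise so the full pipeline is testable without access to the original
    recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
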