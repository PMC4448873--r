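Package: flocknet
Title: Fission-Fusion Group Inference and Phenotypic Assortment from
    Detection Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs fission-fusion group structure from timestamped
    individual detection streams (e.g. PIT-tag reads at automated feeding
    stations), builds weighted social networks with the simple-ratio
    association index, and attributes phenotypic assortment to social
    versus spatial processes by contrasting a phenotypic node-label
    permutation with a spatio-temporally restricted data-stream
    permutation. Includes a lagged group-stability statistic,
    group-composition and size-assortment summaries, saturating models of
    group size against local population size, and a synthetic-data
    generator with planted social and spatial effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    mclust,
    minpack.lm,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
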