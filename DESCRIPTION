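Package: clustermod
Title: Discovery and Co-Expression Validation of Plant Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discovering candidate plant
    biosynthetic gene clusters (BGCs) from gene annotation tables, validating
    them with co-pathway (MetaCyc pathway/reaction) and co-expression criteria
    against a genome-wide Pearson-correlation null, and characterising their
    regulation with a weighted gene co-expression network: soft-threshold
    adjacency, topological overlap, module detection by tree cut, module
    eigengenes, module-trait correlation against BGC member genes, hub-gene
    selection by module membership, gene significance and intramodular
    connectivity, regulator-cluster co-expression matrices, and hypergeometric
    term enrichment. Includes a synthetic-data generator that plants clusters,
    co-expression modules, hubs and regulators with a ground-truth ledger, so
    every stage of the pipeline can be scored for recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
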