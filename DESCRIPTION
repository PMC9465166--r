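Package: herbscreen
Title: Two-Level Screening of Traditional Chinese Medicines for
    Hepatoprotective Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for identifying hepatoprotective
    traditional Chinese medicines (TCMs) at two levels. At the molecule
    level it builds structure-activity models for hepatoprotection from
    labelled SMILES tables (descriptor computation behind a pluggable
    provider, shadow-feature relevance selection, correlation pruning, a
    seven-learner voting ensemble evaluated by stratified cross-validation)
    and mines structural alerts - fragments enriched in hepatoprotective
    ingredients - scored by likelihood ratio. At the herb level it encodes
    TCM drug properties (natures, flavors, channel tropisms) as 24-bit
    vectors, contrasts hepatoprotective and non-hepatoprotective herbs by
    chi-squared tests, mines property-to-activity association rules with
    Apriori, builds bipartite herb-ingredient networks, and intersects a
    material-basis filter (herbs rich in active ingredients) with a
    drug-property verdict (hierarchical-cluster branch classification) to
    nominate candidate hepatoprotective TCMs. A synthetic-data module
    generates desk-scale compound, herb and network inputs with planted
    signal so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
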