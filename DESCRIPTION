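Package: ethnoconsensus
Title: Consensus Statistics and Network Analysis for Ethnobotanical Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of ethnomedicinal field
    surveys built around the use report, one informant citing one plant
    species for one ailment. Computes the informant consensus factor (ICF)
    per ailment category and the fidelity level (FL) per species-ailment
    pair, together with the descriptive frequency tabulations common in
    ethnopharmacology (plant parts, preparation modes, administration
    routes, family representation). Builds the two-mode ailment-category by
    species network, exports it in the UCINET DL full-matrix dialect as
    well as GraphML and edge lists, projects it onto ailment categories,
    lays it out with a seeded force-directed embedding, and groups
    categories by greedy modularity maximisation. A seeded
    Dirichlet-multinomial survey generator produces synthetic datasets with
    controlled informant consensus so every pipeline stage can be tested
    without access to raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    purrr,
    rlang,
    stringr,
    igraph,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
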