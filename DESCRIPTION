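Package: agecourse
Title: Cross-Species Ageing Transcriptomics: Consensus Differential
    Expression, Combined Fuzzy Course Clustering and Lifespan Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening conserved age-regulated genes across species
    from bulk RNA-seq count matrices. Implements a consensus differential
    expression rule combining two negative-binomial pairwise tests and an
    omnibus likelihood-ratio test across three ages, lifespan-rescaled
    combined fuzzy c-means clustering of orthologous expression courses with
    cluster-number selection by a vote of validity indices, orthology
    intersection to call conserved up- and downregulated gene sets, Monte
    Carlo gene-set overlap testing, reaction-level metabolic pathway
    enrichment, promoter scanning with position-specific scoring matrices and
    exact score p-values, and Kaplan-Meier/log-rank statistics with an
    effect-categorization scheme for RNAi lifespan screens. Ships a
    synthetic-data module that emulates the statistical structure of the
    three-species design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
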