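Package: traitnet
Title: Network Analysis of Biological Traits for Response Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds trait co-occurrence networks from species-by-trait-modality
    tables and community samples, following the network-analysis-of-traits
    approach to response diversity. Trait pairs are screened with an exact
    probabilistic (hypergeometric) co-occurrence model, networks are built per
    site and treatment with edge weights equal to the number of species sharing
    each trait pair, and network complexity is summarised as mean node
    eigencentrality on a pooled all-networks graph. Downstream tools compute
    treatment effect sizes relative to controls, one- and two-sample t-tests,
    and quantile-regression summaries of how effect-size variance changes with
    baseline network complexity. A seeded synthetic-data generator emulates a
    multi-site nutrient-enrichment field design for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
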