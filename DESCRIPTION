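Package: paradiv
Title: Comparative Parasite Community Richness and Life-Cycle Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing metazoan parasite communities across marine
    ecosystems from host-dissection data. Harmonizes dissection tables with a
    consistent inclusion protocol (minimum host sample sizes, focal host groups
    and parasite taxa, removal of potentially redundant life stages), estimates
    parasite richness within host species with the Chao2 incidence-based
    estimator, builds analytic sample-based species-accumulation curves with
    host species as the sampling unit, tests an ordered ecosystem hypothesis
    with a stratified-permutation rank analysis of covariance, and compares
    life-cycle (direct versus indirect) and life-stage composition between
    ecosystems with contingency-table chi-square tests. A synthetic
    dissection-data generator with a configurable ordered ecosystem effect
    makes every stage of the pipeline testable without external data.
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
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
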