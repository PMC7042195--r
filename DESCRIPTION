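Package: asdscreen
Title: Cost-Effectiveness of Presymptomatic MRI Screening for Autism in
    High-Risk Infant Siblings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid decision-tree/Markov cohort model comparing strategies
    for assigning early intensive behavioural intervention (EIBI) to infant
    siblings of children with autism spectrum disorder (ASD): the status quo,
    MRI-based screening at 6 or 12 months of age, and treating every
    high-risk child. The decision tree converts test characteristics and the
    risk-ratio effect of early intervention on intellectual disability (ID)
    into lifetime outcome mixtures; a two-state live-or-die Markov cohort
    model accrues discounted quality-adjusted life years and age-banded
    ASD-related costs from age 6 over a life table. The package computes
    incremental cost-effectiveness ratios, the dominance frontier, net
    monetary benefit, one-way (tornado) and probabilistic (Monte Carlo)
    sensitivity analyses, and ships a synthetic Gompertz-Makeham life table
    so every stage runs without external data.
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
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
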