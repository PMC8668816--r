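Package: birdabund
Title: Assemblage-Level Abundance Change from Multi-Scheme Bird Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts heterogeneous national population trend and size
    reports (Article-12 style min/max/best interval estimates) and annual
    population index series (PECBMS style, with standard errors and
    population-coverage fractions) into species-level abundance time series
    for the European Union, aggregates them into assemblage totals with
    bootstrap confidence intervals, and computes change summaries: net and
    gross change, percent and per-annum change, the distribution of species
    log growth rates, covariate disaggregations, extreme-species
    contributions, and piecewise (breakpoint) regression on the log scale.
    Includes a synthetic-data generator with known ground truth so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    purrr,
    rlang,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
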