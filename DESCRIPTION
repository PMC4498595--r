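Package: wetlandprior
Title: Boom-Bust Wetland Prioritisation for Waterbirds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systematic conservation planning for wetlands in boom-bust
    (wet/dry phase) river systems. Implements stochastic minimum-set reserve
    selection with per-species proportional abundance targets (simulated
    annealing with a feasibility repair pass, plus greedy and exact oracles),
    selection-frequency irreplaceability, representation-target sweeps with
    cost-effectiveness knees, per-year prioritisation with flow-quantile
    wet/dry phase classification and refugia/breeding functional classes,
    area-corrected wetland-type irreplaceability with a chi-squared contrast,
    and BIC-approximate Bayesian model averaging of water-availability
    drivers. Includes a synthetic boom-bust waterbird abundance generator
    with known ground-truth refugia and breeding structure, and readers and
    writers for the Marxan pu/spec/puvspr file dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
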