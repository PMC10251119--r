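Package: driftbalance
Title: Quantifying the Balance Between Ecological Drift and Selection in
    Simulated Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale agent-based biofilm simulator of identical
    heterotrophic bacteria growing under low-nutrient conditions, together
    with the statistical pipeline that quantifies how much of a Monod
    kinetic advantage (maximum specific growth rate or half-saturation
    constant) a drift-doomed lineage needs to overcome bad luck. Runs are
    seed-deterministic via a Park-Miller random number stream so that the
    "biggest loser" of a neutral run can be re-run with altered kinetics
    under identical randomness. Downstream stages aggregate re-run outcomes
    into thriving-probability maps, extract logistic threshold parameters
    (mu50, steepness, spread95/spread68), regress them on the
    half-saturation change, and fit descriptive multiple linear regression
    and generalized additive models over the full factor space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
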