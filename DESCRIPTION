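Package: stoichdemo
Title: Demographic and Stoichiometric Analysis of Phosphorus-Limitation
    Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing phosphorus-supplementation feeding trials
    on planktonic rotifers: an individual-based generator of life-table
    event logs, serial-transfer census series, morphometric and elemental
    composition tables; construction of age-classed survivorship and
    fecundity schedules from interval-censored event data; intrinsic rate
    of increase via the Euler-Lotka equation and exponential growth rates
    from daily census ratios; ellipsoid body and egg volumes and somatic
    growth rates; molar C:N:P ratios; and a decomposition of food-quality
    effects into direct (stoichiometric) and indirect (non-stoichiometric)
    components with replicate-level bootstrap uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
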