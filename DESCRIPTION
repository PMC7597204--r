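Package: umwalk
Title: Ultrametric Random Walks on Social Trees for Epidemic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models disease spread across a hierarchically clustered population
    as a continuous-time random walk on a p-adic tree of social clusters.
    Hops between clusters are controlled by social barriers that grow with the
    number of hierarchy levels crossed; the master equation of the walk is
    solved exactly through the analytic spectrum of the hierarchical rate
    matrix. Provides the ultrametric social space and its ball partitions,
    barrier profiles and generators, exact and spectral solvers with a
    matrix-exponential oracle, an event-driven stochastic simulator, and
    epidemic observables: infection probability, herd immunity curves,
    spreading entropy, power-law exponent fits, and mean social distance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), ape, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
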