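Package: cetipm
Title: Integrated Population Models for Cetacean Trend Estimation in Shifting Habitat
Version: 0.1.0
Authors@R:
    person("cetipm", "developers", email = "cetipm@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian estimation tools for assessing cetacean
    population trends when surveys cover only part of a shifting range.
    Simulates a geographically closed large-whale population distributed over
    a spatially autocorrelated habitat grid under stable or declining vital
    rates and random or shifting habitat, simulates line-transect distance
    sampling, photo-identification mark-recapture from the survey platform,
    and robust-design small-boat studies, and fits a ladder of integrated
    population models (distance sampling only, plus calf index, plus
    mark-recapture from one or two platforms) by Markov chain Monte Carlo.
    Includes WAIC model comparison, change-in-trend posterior summaries, and
    Gelman-Rubin and Geweke convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
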