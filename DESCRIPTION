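Package: edmchaos
Title: Partitioning Prediction Error in Replicated Time Series into
    Stochasticity, Nonlinearity, and Chaos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Empirical dynamic modeling (simplex projection and S-map
    forecasting) for replicated ecological time series, with
    cross-prediction between experimental replicates that differ only in
    initial abundances, Lyapunov-exponent estimation from the growth of
    forecast error with prediction horizon, and a decomposition of mean
    squared prediction error into fractions attributable to
    nonlinearity, chaos, and stochasticity. Includes generators for
    stochastic predator-prey replicates, discrete-time growth maps with
    tunable chaos and process noise, and linear benchmark series, plus a
    config-driven pipeline that reproduces the full analysis as tidy
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
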