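Package: phasefill
Title: Phase-Space-Guided Stochastic Interpolation of Sparse Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gap filling for sparsely sampled univariate time series using
    multi-point fractional Brownian bridges, i.e. fractional Brownian motion
    conditioned to pass exactly through the observed points. A genetic
    algorithm searches over a population of bridge interpolations with random
    Hurst exponents for the candidate whose Takens delay-embedded trajectory
    is smoothest, measured as the variance of second-derivative magnitudes
    along the reconstructed phase-space curve. Includes a Lorenz-system
    benchmark harness with linear and cubic-spline baselines, delay and
    embedding-dimension estimators, and a synthetic seasonal fixture
    generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
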