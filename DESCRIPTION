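Package: hetspike
Title: Spiking Networks and Mean-Field Models with Quenched Spike-Threshold
    Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of Izhikevich neurons whose spike thresholds
    carry quenched disorder drawn from truncated Lorentzian or Gaussian
    distributions, and integrates the corresponding four-dimensional
    (rate, voltage, recovery, synapse) mean-field equations for single and
    coupled populations. Ships the analysis pipelines needed to study how
    threshold heterogeneity reshapes population dynamics and computation:
    grid- and ramp-based detection of fold and Hopf bifurcations, persistence
    of localized activity bumps on ring networks, reservoir-computing
    function generation with a ridge readout (participation-ratio
    dimensionality and response-kernel variance), and phase-locking analysis
    of the periodically forced mean-field model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
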