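Package: sarsyn
Title: Synchronous-Asynchronous Neurotransmitter Release: Simulation and Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation and inverse inference for a stochastic
    extension of the Tsodyks-Markram short-term-plasticity synapse model in
    which a second, slower Ca2+-sensor pathway drives asynchronous vesicle
    release from the same readily-releasable pool. Provides a binomial
    quantal simulator and its deterministic mean-field counterpart, an
    exponential receptor model mapping release to postsynaptic current,
    IPSC preprocessing (leak subtraction, kernel estimation) and a
    sequential constrained deconvolution recovering scaled release rates,
    period-based Gaussian-likelihood grid-search parameter fitting with
    likelihood-ratio confidence intervals, Fano-factor quantal-size
    estimation, and a parameter-recovery simulation study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
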