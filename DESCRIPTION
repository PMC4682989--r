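Package: rdsvar
Title: Sampling-Variance Estimation for Respondent-Driven Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the sampling variance of respondent-driven
    sampling (RDS) and random-walk sampling on social networks. Provides the
    exact spectral sampling variance of a stationary random walk on a known
    network or Markov chain, the Volz-Heckathorn (VHE) and Salganik bootstrap
    (SBE) variance estimators together with branching-distance and
    higher-order-Markov corrections, a regression-based diagnostic for the
    first-order Markov (FOM) assumption, a two-block network generator with a
    hidden variable structuring cross-group mixing, a branching RDS simulator,
    and replicated-study drivers computing bias, ratio, coverage and design
    effect summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
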