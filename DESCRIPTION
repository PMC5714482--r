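Package: flucassay
Title: Likelihood Inference for Luria-Delbruck Fluctuation Assays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood analysis of fluctuation assay (Luria-Delbruck)
    mutant-count data. Mutant-count distributions are defined through their
    probability generating functions and evaluated by power-series recursions:
    the Lea-Coulson model, the Mandelbrot-Koch model with differential mutant
    fitness, the partial-plating model, and a gamma-mixture model absorbing
    culture-to-culture variability in final population size. Provides
    Newton-Raphson maximum-likelihood estimation of the expected number of
    mutations per culture (and jointly of mutant relative fitness), profile
    likelihood-ratio confidence intervals, P0-method estimators with a
    partial-plating correction, a likelihood-ratio test for equality of
    mutation rates between experiments with unequal final population sizes,
    a compound-Poisson experiment simulator with Monte-Carlo power analysis,
    and experiment-design calculators (overflow index, precision-based
    sample size).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
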