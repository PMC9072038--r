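Package: stfh
Title: Spatio-Temporal Fay-Herriot Models for Small Area Estimation
Version: 1.0.0
Authors@R: person("STFH", "Developers", role = c("aut", "cre"),
    email = "stfh-dev@example.org")
Description: Area-level small area estimation with the Fay-Herriot model and
    its spatial (SAR(1) area effects) and spatio-temporal (SAR(1) x AR(1))
    extensions. Fits variance components by restricted maximum likelihood,
    produces empirical best linear unbiased predictors (EBLUPs) for every
    area-by-period cell, and estimates their mean squared error analytically
    (Fay-Herriot) or by parametric bootstrap (spatial and spatio-temporal
    models). Includes the standard diagnostic battery (information criteria,
    Kolmogorov-Smirnov normality check, bias-diagnostic regression, percent
    coefficient of variation and efficiency-gain summaries), a synthetic
    zone-by-year panel generator with known truth for validation, delimited
    text input/output for panels and proximity structures, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
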