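Package: selscape
Title: Selection Surfaces, Trait Covariance, and Macroevolutionary Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking nonlinear (sexual) selection surfaces to intraspecific
    phenotypic covariance and interspecific divergence in multivariate trait space.
    Estimates Lande-Arnold linear and quadratic selection gradients from
    individual fitness data, rotates the gamma matrix to canonical axes with
    permutation tests on the eigenvalues, and locates the dominant surface
    direction by projection pursuit with smoothing splines. Estimates the
    phenotypic covariance matrix P (with delete-one jackknife standard errors and
    pooled multi-year standardization) and the divergence matrix D from taxon
    means, then quantifies alignment among gamma, P, and D via vector
    correlations with permutation nulls, directional variances e(m) = m'Am, and
    the Flury common-principal-components hierarchy (equality, proportionality,
    CPC, partial CPC, unrelated) with AIC model building and jump-up tests. A
    Mahalanobis index summarises multivariate sexual dimorphism per taxon, and a
    synthetic-data generator reproduces the statistical structure of each input
    so the full pipeline is testable without field data. Ships transcriptions of
    the published Phymata trait tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
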