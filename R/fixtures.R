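#' Published Phymata trait summaries and matrices
#'
#' Accessors for the published trait tables of the ambush-bug study system:
#' museum trait distributions for 37 Phymata taxa, the variance-standardized
#' sexual selection gradients for *P. americana americana*, the
#' mean-standardized phenotypic covariance matrix **P** (108 common-garden
#' males), the divergence matrix **D** (37 taxon means), and the canonical
#' axes of the mean-standardized selection surface.
#'
#' All matrices are returned on the computation scale: the published **P**
#' was multiplied by 100 and **D** by 10 for readability, and those factors
#' are divided back out here.
#'
#' @param corrected If `TRUE` (default) the taxon table with one typographic
#'   SD ("0190", read as 0.190) repaired is returned; `FALSE` returns the
#'   verbatim transcription. SDs do not enter any divergence computation.
#' @name phymata_fixtures
NULL

.phymata_traits <- c("PN", "MD", "ML")

.sym3 <- function(lower, labels = .phymata_traits) {
  A <- diag(3)
  A[lower.tri(A, diag = TRUE)] <- lower
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  dimnames(A) <- list(labels, labels)
  A
}

#' @rdname phymata_fixtures
#' @return `phymata_taxa()`: tibble with columns `taxon`, `n`, and
#'   `<trait>_mean` / `<trait>_sd` for PN (mm), MD and ML (0-255 darkness).
#' @export
phymata_taxa <- function(corrected = TRUE) {
  f <- if (corrected) "phymata_taxon_means.csv" else
    "phymata_taxon_means_verbatim.csv"
  read_taxon_means(system.file("extdata", f, package = "selscape",
                               mustWork = TRUE))
}

#' @rdname phymata_fixtures
#' @return `phymata_reference_means()`: named vector of the
#'   *P. americana americana* museum trait means used as the
#'   mean-standardization reference.
#' @export
phymata_reference_means <- function() {
  c(PN = 3.10, MD = 236.13, ML = 213.40)
}

#' @rdname phymata_fixtures
#' @return `phymata_beta()`: named vector of variance-standardized linear
#'   gradients.
#' @export
phymata_beta <- function() {
  c(PN = 0.008, MD = -0.029, ML = 0.021)
}

#' @rdname phymata_fixtures
#' @return `phymata_gamma()`: the variance-standardized quadratic/
#'   correlational gradient matrix.
#' @export
phymata_gamma <- function() {
  .sym3(c(0.137, 0.005, -0.118, -0.365, 0.214, -0.206))
}

#' @rdname phymata_fixtures
#' @param se If `TRUE`, attach the published element-wise standard errors as
#'   attribute `"se"`.
#' @return `phymata_P()`: mean-standardized phenotypic covariance matrix
#'   (published values divided by 100), as a [trait_cov] object with n = 108.
#' @export
phymata_P <- function(se = TRUE) {
  M <- .sym3(c(0.243, 0.016, -0.063, 0.265, 0.421, 2.717)) / 100
  SE <- if (se) .sym3(c(0.034, 0.026, 0.075, 0.048, 0.096, 0.340)) / 100
        else NULL
  new_trait_cov(M, n = 108, kind = "P", scale_tag = "mean_standardized",
                se = SE)
}

#' @rdname phymata_fixtures
#' @param source `"means"` for the covariance among taxon means (the default,
#'   used in every matrix comparison here) or `"mixed"` for the published
#'   REML mixed-model estimate.
#' @return `phymata_D()`: mean-standardized divergence matrix (published
#'   values divided by 10), as a [trait_cov] object with n = 37 taxa.
#' @export
phymata_D <- function(source = c("means", "mixed")) {
  source <- match.arg(source)
  if (source == "means") {
    M <- .sym3(c(0.335, 0.036, -0.017, 0.100, 0.026, 0.236)) / 10
    se <- NULL
  } else {
    M <- .sym3(c(0.308, -0.007, -0.033, 0.095, 0.045, 0.334)) / 10
    se <- .sym3(c(0.083, 0.033, 0.057, 0.028, 0.034, 0.078)) / 10
  }
  new_trait_cov(M, n = 37, kind = "D", scale_tag = "mean_standardized",
                se = se)
}

#' @rdname phymata_fixtures
#' @return `phymata_m_vectors()`: 3 x 3 matrix whose columns `m1`, `m2`,
#'   `m_max` are the canonical axes of the mean-standardized selection
#'   surface (unit vectors; loadings on PN, MD, ML).
#' @export
phymata_m_vectors <- function() {
  m <- cbind(m1 = c(0.365, 0.704, 0.609),
             m2 = c(0.922, -0.184, -0.341),
             m_max = c(0.128, -0.686, 0.716))
  rownames(m) <- .phymata_traits
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' @rdname phymata_fixtures
#' @return `phymata_canonical_table()`: tibble of the published canonical
#'   analysis of the variance-standardized surface (theta, lambda, loadings).
#' @export
phymata_canonical_table <- function() {
  tibble::tibble(
    axis = c("m1", "m2", "m3"),
    theta = c(0.004, 0.001, 0.037),
    lambda = c(0.181, -0.094, -0.522),
    PN = c(0.926, 0.361, 0.111),
    MD = c(-0.131, 0.581, -0.803),
    ML = c(-0.354, 0.729, 0.585)
  )
}
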