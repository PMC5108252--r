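#' Extract a complete-case trait matrix from a data frame
#'
#' Rows with a missing value in any trait column are dropped (with a message
#' giving the count); no imputation is attempted.
#'
#' @param data A data frame with one row per individual (or taxon).
#' @param traits Character vector of trait column names, in the order the
#'   matrix columns should take. Default `c("PN", "MD", "ML")`.
#' @return A numeric matrix with one column per trait.
#' @export
trait_matrix <- function(data, traits = c("PN", "MD", "ML")) {
  missing_cols <- setdiff(traits, names(data))
  if (length(missing_cols) > 0) {
    stop("trait column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  Z <- as.matrix(as.data.frame(data)[, traits, drop = FALSE])
  if (!is.numeric(Z)) stop("trait columns must be numeric", call. = FALSE)
  keep <- stats::complete.cases(Z)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " row(s) with missing trait values")
    Z <- Z[keep, , drop = FALSE]
  }
  if (ncol(Z) < 2) stop("at least two traits are required", call. = FALSE)
  Z
}

#' Standardize trait columns
#'
#' Three scalings are supported, each recorded in a `"scaling"` attribute so
#' the transformation can be inverted:
#' \describe{
#'   \item{variance}{per column, subtract the mean and divide by the sample
#'     standard deviation (n - 1 denominator); the scale on which
#'     Lande-Arnold gradients are conventionally reported.}
#'   \item{mean}{divide each column by a (strictly positive) reference mean,
#'     either supplied via `reference` or the column's own mean; puts traits
#'     in proportional, unit-free terms so that selection, variation and
#'     divergence are comparable.}
#'   \item{log}{elementwise natural log (values must be positive).}
#' }
#'
#' When `by` names a grouping column, standardization is applied separately
#' within each group (e.g. within year), which removes differences in
#' multivariate means between groups before pooling.
#'
#' @param data Data frame containing the trait columns.
#' @param traits Trait column names.
#' @param scheme One of `"variance"`, `"mean"`, `"log"`.
#' @param by Optional name of a grouping column for within-group
#'   standardization.
#' @param reference Optional named numeric vector of reference means for
#'   `scheme = "mean"` (names matching `traits`). If `NULL`, each column's
#'   own mean is used and standardized columns have mean 1.
#' @return `data` as a tibble with the trait columns replaced by their
#'   standardized values; attribute `"scaling"` holds the scheme and the
#'   per-group means/SDs used.
#' @examples
#' d <- data.frame(PN = c(1, 2, 3), MD = c(10, 20, 30), ML = c(5, 6, 7))
#' standardize_traits(d, scheme = "variance")$PN
#' @export
standardize_traits <- function(data, traits = c("PN", "MD", "ML"),
                               scheme = c("variance", "mean", "log"),
                               by = NULL, reference = NULL) {
  scheme <- match.arg(scheme)
  out <- tibble::as_tibble(data)
  if (!is.null(by) && !by %in% names(out)) {
    stop("grouping column '", by, "' not found", call. = FALSE)
  }
  groups <- if (is.null(by)) factor(rep("all", nrow(out))) else factor(out[[by]])
  spec <- list(scheme = scheme, traits = traits, by = by, groups = list())

  for (g in levels(groups)) {
    idx <- which(groups == g)
    rec <- list()
    for (tr in traits) {
      x <- out[[tr]][idx]
      if (anyNA(x)) stop("missing values in trait '", tr,
                         "'; drop or complete rows first", call. = FALSE)
      if (scheme == "variance") {
        s <- stats::sd(x)
        if (!is.finite(s) || s <= 0) {
          stop("trait '", tr, "' has zero variance", if (!is.null(by))
            paste0(" in group '", g, "'") else "", call. = FALSE)
        }
        m <- mean(x)
        out[[tr]][idx] <- (x - m) / s
        rec[[tr]] <- c(mean = m, sd = s)
      } else if (scheme == "mean") {
        m <- if (is.null(reference)) mean(x) else {
          if (is.null(names(reference)) || !tr %in% names(reference)) {
            stop("'reference' must be a named vector covering all traits",
                 call. = FALSE)
          }
          reference[[tr]]
        }
        if (!is.finite(m) || m <= 0) {
          stop("non-positive reference mean for trait '", tr, "'",
               call. = FALSE)
        }
        out[[tr]][idx] <- x / m
        rec[[tr]] <- c(mean = m)
      } else {
        if (any(x <= 0)) {
          bad <- idx[which(x <= 0)[1]]
          stop("non-positive value for trait '", tr, "' (row ", bad,
               "); cannot log-transform", call. = FALSE)
        }
        out[[tr]][idx] <- log(x)
        rec[[tr]] <- c()
      }
    }
    spec$groups[[g]] <- rec
  }
  attr(out, "scaling") <- spec
  out
}

#' Invert a mean standardization
#'
#' Multiplies mean-standardized trait columns back by the reference means
#' recorded by [standardize_traits()].
#'
#' @param data A tibble produced by `standardize_traits(..., scheme = "mean")`.
#' @return The tibble on the original scale.
#' @export
unstandardize_traits <- function(data) {
  spec <- attr(data, "scaling")
  if (is.null(spec) || spec$scheme != "mean") {
    stop("'data' must carry a mean-standardization scaling attribute",
         call. = FALSE)
  }
  out <- data
  groups <- if (is.null(spec$by)) factor(rep("all", nrow(out)))
            else factor(out[[spec$by]])
  for (g in levels(groups)) {
    idx <- which(groups == g)
    for (tr in spec$traits) {
      out[[tr]][idx] <- out[[tr]][idx] * spec$groups[[g]][[tr]][["mean"]]
    }
  }
  attr(out, "scaling") <- NULL
  out
}

#' Read an individual-level trait table
#'
#' Expects a UTF-8 CSV with a header row and "." decimal separator. Typical
#' columns: `id`, `taxon`, `sex`, `year`, the trait columns (default PN in
#' mm, MD and ML in 0-255 darkness units) and a fitness column such as
#' `fitness` or `mating_success`.
#'
#' @param path CSV file path.
#' @param traits Trait columns that must be present.
#' @return A tibble.
#' @export
read_individuals <- function(path, traits = c("PN", "MD", "ML")) {
  x <- utils::read.csv(path, fileEncoding = "UTF-8")
  missing_cols <- setdiff(traits, names(x))
  if (length(missing_cols) > 0) {
    stop("input lacks trait column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' Read a taxon-mean summary table
#'
#' Expects columns `taxon`, `n`, and `<trait>_mean` / `<trait>_sd` for each
#' trait (e.g. `PN_mean`, `PN_sd`). Taxa with fewer than `min_n` specimens
#' are dropped with a message, mirroring the minimum-males inclusion rule for
#' museum material.
#'
#' @param path CSV file path.
#' @param traits Trait names.
#' @param min_n Minimum per-taxon sample size to retain (default 4).
#' @return A tibble, one row per retained taxon.
#' @export
read_taxon_means <- function(path, traits = c("PN", "MD", "ML"), min_n = 4) {
  x <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
  need <- c("taxon", "n", paste0(traits, "_mean"))
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("taxon table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  drop <- x$n < min_n
  if (any(drop)) {
    message("dropping ", sum(drop), " taxon/taxa with n < ", min_n)
    x <- x[!drop, , drop = FALSE]
  }
  x
}
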