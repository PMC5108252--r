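#' Labelled covariance matrix container
#'
#' A thin S3 wrapper for the symmetric matrices the package passes around
#' (**P**, **D**, or a gamma matrix): the matrix itself, its effective sample
#' size, a scale tag, and optional element-wise standard errors.
#'
#' @param matrix Symmetric numeric matrix.
#' @param n Sample size behind the estimate (individuals or taxa).
#' @param kind One of `"P"`, `"D"`, `"gamma"`, `"other"`.
#' @param scale_tag Character scale description (e.g. `"mean_standardized"`).
#' @param se Optional symmetric matrix of standard errors.
#' @return An object of class `trait_cov` (a list with the fields above).
#' @export
new_trait_cov <- function(matrix, n, kind = "other", scale_tag = "raw",
                          se = NULL) {
  if (!isSymmetric(unname(matrix), tol = 1e-12)) {
    stop("covariance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(matrix) < 0)) stop("negative diagonal element", call. = FALSE)
  if (n < 2) stop("sample size must be at least 2", call. = FALSE)
  structure(list(matrix = matrix, n = n, kind = kind, scale_tag = scale_tag,
                 se = se, traits = colnames(matrix)),
            class = "trait_cov")
}

#' @export
print.trait_cov <- function(x, ...) {
  cat(sprintf("<trait_cov: %s, n = %d, scale = %s>\n", x$kind, x$n,
              x$scale_tag))
  print(round(x$matrix, 6))
  invisible(x)
}

#' @export
as.matrix.trait_cov <- function(x, ...) x$matrix

#' @exportS3Method generics::tidy
tidy.trait_cov <- function(x, ...) {
  m <- x$matrix
  tr <- colnames(m) %||% paste0("z", seq_len(ncol(m)))
  out <- tibble::as_tibble(as.data.frame(as.table(m)),
                           .name_repair = ~c("row", "col", "value"))
  out$row <- tr[as.integer(out$row)]
  out$col <- tr[as.integer(out$col)]
  if (!is.null(x$se)) out$se <- as.vector(x$se)
  out
}

.cov_input <- function(A) if (inherits(A, "trait_cov")) A$matrix else as.matrix(A)

#' Estimate the phenotypic covariance matrix P
#'
#' Computes the sample covariance (n - 1 denominator) of the trait columns.
#' With `pool_by`, traits are first mean-standardized separately within each
#' group (each group's column means become 1), which removes between-group
#' differences in multivariate means before pooling — the device used to
#' combine common-garden samples reared in different years without inflating
#' variance along the direction separating the yearly means.
#'
#' @param data Data frame of individuals.
#' @param traits Trait column names.
#' @param pool_by Optional grouping column (e.g. `"year"`).
#' @param jackknife If `TRUE`, attach delete-one jackknife standard errors
#'   for every matrix element.
#' @return A [new_trait_cov()] object of kind `"P"` with `n` = total rows.
#' @export
p_matrix <- function(data, traits = c("PN", "MD", "ML"), pool_by = NULL,
                     jackknife = FALSE) {
  scale_tag <- "raw"
  if (!is.null(pool_by)) {
    counts <- table(data[[pool_by]])
    if (any(counts < 3)) {
      stop("each '", pool_by, "' group needs at least 3 rows", call. = FALSE)
    }
    data <- standardize_traits(data, traits, scheme = "mean", by = pool_by)
    scale_tag <- "mean_standardized"
  }
  Z <- trait_matrix(data, traits)
  if (nrow(Z) < 3) stop("at least 3 rows are required", call. = FALSE)
  M <- stats::cov(Z)
  se <- if (jackknife) jackknife_se_cov(Z) else NULL
  new_trait_cov(M, n = nrow(Z), kind = "P", scale_tag = scale_tag, se = se)
}

#' Delete-one jackknife standard errors for a covariance matrix
#'
#' For each element of the sample covariance matrix, recomputes the estimate
#' with each row deleted in turn and returns
#' \eqn{\sqrt{\frac{n-1}{n} \sum_i (\theta_{(i)} - \bar\theta_{(\cdot)})^2}}.
#'
#' @param Z Numeric matrix, rows = individuals.
#' @return Symmetric matrix of standard errors.
#' @export
jackknife_se_cov <- function(Z) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n < 3) stop("jackknife needs at least 3 rows", call. = FALSE)
  p <- ncol(Z)
  reps <- array(NA_real_, c(n, p, p))
  for (i in seq_len(n)) reps[i, , ] <- stats::cov(Z[-i, , drop = FALSE])
  mbar <- apply(reps, c(2, 3), mean)
  dev2 <- sweep(reps, c(2, 3), mbar)^2
  se <- sqrt((n - 1) / n * apply(dev2, c(2, 3), sum))
  dimnames(se) <- dimnames(stats::cov(Z))
  se
}

#' Divergence matrix D from taxon means
#'
#' Divides each taxon's trait-mean vector elementwise by the reference means
#' and takes the sample covariance (n - 1) across taxa. Taxa are weighted
#' equally regardless of how many specimens their means were computed from.
#'
#' @param taxa Tibble as returned by [read_taxon_means()] or
#'   [phymata_taxa()]: columns `taxon`, `n`, `<trait>_mean`.
#' @param traits Trait names.
#' @param reference Either a named numeric vector of reference means or the
#'   name of a taxon in `taxa` whose means are used.
#' @param min_n Taxa with fewer specimens are dropped (default 4).
#' @return A [new_trait_cov()] object of kind `"D"`, `n` = number of taxa.
#' @export
d_matrix <- function(taxa, traits = c("PN", "MD", "ML"),
                     reference = "P. americana americana", min_n = 4) {
  mcols <- paste0(traits, "_mean")
  missing_cols <- setdiff(mcols, names(taxa))
  if (length(missing_cols) > 0) {
    stop("taxon table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if ("n" %in% names(taxa)) {
    drop <- taxa$n < min_n
    if (any(drop)) {
      message("dropping ", sum(drop), " taxon/taxa with n < ", min_n)
      taxa <- taxa[!drop, , drop = FALSE]
    }
  }
  if (nrow(taxa) < 3) stop("at least 3 taxa are required", call. = FALSE)
  M <- as.matrix(taxa[, mcols, drop = FALSE])
  colnames(M) <- traits
  bad <- !stats::complete.cases(M)
  if (any(bad)) {
    stop("taxon with missing trait mean: ",
         paste(taxa$taxon[bad], collapse = ", "), call. = FALSE)
  }
  if (is.character(reference)) {
    hit <- which(taxa$taxon == reference)
    if (length(hit) != 1) {
      stop("reference taxon '", reference, "' not found", call. = FALSE)
    }
    ref <- M[hit, ]
  } else {
    ref <- reference[traits]
    if (length(ref) != length(traits)) ref <- as.numeric(reference)
  }
  if (any(!is.finite(ref)) || any(ref <= 0)) {
    stop("reference means must be positive", call. = FALSE)
  }
  Ms <- sweep(M, 2, ref, "/")
  new_trait_cov(stats::cov(Ms), n = nrow(Ms), kind = "D",
                scale_tag = "mean_standardized")
}

#' Mean-standardized taxon-mean matrix
#'
#' The rows that [d_matrix()] takes the covariance of: taxon means divided by
#' the reference means. Useful as input to [alignment_test()] on the
#' divergence matrix.
#'
#' @inheritParams d_matrix
#' @return Numeric matrix, one row per taxon, columns = traits.
#' @export
taxon_mean_matrix <- function(taxa, traits = c("PN", "MD", "ML"),
                              reference = "P. americana americana",
                              min_n = 4) {
  mcols <- paste0(traits, "_mean")
  if ("n" %in% names(taxa)) taxa <- taxa[taxa$n >= min_n, , drop = FALSE]
  M <- as.matrix(taxa[, mcols, drop = FALSE])
  colnames(M) <- traits
  rownames(M) <- taxa$taxon
  if (is.character(reference)) {
    ref <- M[match(reference, taxa$taxon), ]
  } else {
    ref <- as.numeric(reference[traits])
  }
  sweep(M, 2, ref, "/")
}

#' Moment-based divergence matrix from individual-level data
#'
#' One-way multivariate analysis-of-variance moment estimator of the
#' between-taxon covariance: \eqn{\hat D = (MS_b - MS_w) / n_0}, with
#' \eqn{n_0 = (N - \sum_k n_k^2 / N)/(K - 1)} the usual unbalanced-design
#' coefficient. If the estimate has negative eigenvalues it is projected to
#' the positive-semidefinite cone by truncating them at zero (with a
#' warning).
#'
#' @param data Data frame of individuals with a taxon column.
#' @param traits Trait column names.
#' @param taxon Name of the taxon column.
#' @return A [new_trait_cov()] object of kind `"D"`, `n` = number of taxa.
#' @export
d_matrix_moments <- function(data, traits = c("PN", "MD", "ML"),
                             taxon = "taxon") {
  Z <- trait_matrix(data, traits)
  g <- factor(data[[taxon]][stats::complete.cases(
    as.data.frame(data)[, traits, drop = FALSE])])
  K <- nlevels(g)
  if (K < 3) stop("at least 3 taxa are required", call. = FALSE)
  nk <- as.vector(table(g))
  if (sum(nk >= 2) < 2) {
    stop("at least 2 taxa need 2 or more individuals", call. = FALSE)
  }
  N <- sum(nk)
  p <- ncol(Z)
  grand <- colMeans(Z)
  means <- rowsum(Z, g) / nk
  SSB <- crossprod(sweep(means, 2, grand) * sqrt(nk))
  SSW <- matrix(0, p, p)
  for (k in seq_len(K)) {
    Zk <- Z[g == levels(g)[k], , drop = FALSE]
    if (nrow(Zk) > 1) {
      SSW <- SSW + crossprod(sweep(Zk, 2, colMeans(Zk)))
    }
  }
  MSb <- SSB / (K - 1)
  MSw <- SSW / (N - K)
  n0 <- (N - sum(nk^2) / N) / (K - 1)
  D <- (MSb - MSw) / n0
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  if (any(e$values < 0)) {
    warning("moment estimate of D not positive semidefinite; ",
            sum(e$values < 0), " eigenvalue(s) truncated at 0")
    D <- e$vectors %*% diag(pmax(e$values, 0), p) %*% t(e$vectors)
    dimnames(D) <- list(traits, traits)
  }
  new_trait_cov((D + t(D)) / 2, n = K, kind = "D", scale_tag = "raw")
}
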