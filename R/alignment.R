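#' Vector correlation between two directions
#'
#' The absolute cosine of the angle, \eqn{|a \cdot b| / (\|a\| \|b\|)}:
#' 1 for parallel directions, 0 for orthogonal ones. Invariant to sign flips
#' and rescaling of either argument.
#'
#' @param a,b Nonzero numeric vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
vector_correlation <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector", call. = FALSE)
  min(abs(sum(a * b)) / (na * nb), 1)
}

#' Extreme-variance eigenvector of a covariance matrix
#'
#' Returns the unit eigenvector of the smallest (default) or largest
#' eigenvalue — e.g. `p_min`, the direction of least phenotypic variance, or
#' `d_min`, the direction of least interspecific divergence. If the relevant
#' eigenvalue is separated from its neighbour by less than
#' `1e-8 * trace(A)` the direction is ill-determined and a warning is
#' issued. The sign is fixed so the first nonzero loading is positive.
#'
#' @param A Symmetric matrix or [new_trait_cov()] object.
#' @param which `"min"` or `"max"`.
#' @return Unit numeric vector.
#' @examples
#' min_eigenvector(phymata_P())
#' @export
min_eigenvector <- function(A, which = c("min", "max")) {
  which <- match.arg(which)
  A <- .cov_input(A)
  if (!isSymmetric(unname(A), tol = 1e-8)) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  p <- length(e$values)
  i <- if (which == "min") p else 1L
  neighbour <- if (which == "min") p - 1L else 2L
  gap <- abs(e$values[i] - e$values[neighbour])
  if (gap < 1e-8 * abs(sum(diag(A)))) {
    warning("near-degenerate ", which, " eigenvalues (gap ",
            format(gap, digits = 3), "); direction is ill-determined")
  }
  v <- .fix_sign(e$vectors[, i])
  names(v) <- colnames(A)
  v
}

#' Variance in a stated direction
#'
#' The quadratic form \eqn{e(m) = m' A m}: the variance of `A` (a **P** or
#' **D** matrix) projected onto the direction `m`. Analogous to evolvability
#' in a stated direction, but interpreted here purely as directional
#' variance. `m` is renormalized to unit length with a warning if needed.
#'
#' @param A Symmetric matrix or [new_trait_cov()] object.
#' @param m Direction vector.
#' @return A non-negative number (for positive semidefinite `A`).
#' @examples
#' directional_variance(phymata_P(), phymata_m_vectors()[, "m_max"])
#' @export
directional_variance <- function(A, m) {
  A <- .cov_input(A)
  m <- as.numeric(m)
  if (length(m) != ncol(A)) stop("dimension mismatch", call. = FALSE)
  nm <- sqrt(sum(m^2))
  if (nm == 0) stop("zero direction vector", call. = FALSE)
  if (abs(nm - 1) > 1e-8) {
    warning("direction not unit length; renormalizing")
    m <- m / nm
  }
  as.numeric(t(m) %*% A %*% m)
}

#' Average directional variance over random directions
#'
#' Mean and SD of \eqn{m' A m} over `k` directions drawn uniformly on the
#' unit sphere (normalized Gaussian draws). As `k` grows the mean converges
#' to `trace(A) / p`.
#'
#' @param A Symmetric matrix or [new_trait_cov()] object.
#' @param k Number of random directions (at least 2).
#' @param seed Optional integer seed.
#' @return A list with `mean`, `sd`, and `k`.
#' @export
random_direction_average <- function(A, k = 1000, seed = NULL) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  A <- .cov_input(A)
  p <- ncol(A)
  M <- matrix(stats::rnorm(k * p), k, p)
  M <- M / sqrt(rowSums(M^2))
  e <- rowSums((M %*% A) * M)
  list(mean = mean(e), sd = stats::sd(e), k = k)
}

.alignment_result <- function(rho, p_value, reference, target, n_perm, seed,
                              kind) {
  structure(list(rho = rho, p_value = p_value,
                 reference_vector = reference, target_vector = target,
                 n_perm = n_perm, seed = seed, kind = kind),
            class = "alignment_test")
}

#' @export
print.alignment_test <- function(x, ...) {
  cat(sprintf("<alignment_test (%s)> rho = %.4f, p = %.4g (%d permutations)\n",
              x$kind, x$rho, x$p_value, x$n_perm))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.alignment_test <- function(x, ...) {
  tibble::tibble(kind = x$kind, rho = x$rho, p.value = x$p_value,
                 n_perm = x$n_perm)
}

#' Permutation test of alignment between a reference direction and an
#' extreme-variance eigenvector
#'
#' Measures the vector correlation between a fixed reference direction
#' (e.g. `m_max`, treated as error-free) and the minimum- (or maximum-)
#' variance eigenvector of the covariance of `X`, then builds a null by
#' independently shuffling each trait column of `X` (a pure within-trait
#' permutation that destroys covariance while preserving the margins),
#' recomputing the covariance matrix and its designated eigenvector, and
#' recording the correlation with the reference. The p-value is
#' \eqn{(1 + \#\{\rho_{perm} \ge \rho_{obs}\}) / (n_{perm} + 1)}.
#'
#' @param X Numeric matrix or data frame of rows (individuals, or
#'   mean-standardized taxon means from [taxon_mean_matrix()]).
#' @param reference Reference direction (normalized internally).
#' @param which Align with the `"min"` (default) or `"max"` eigenvector.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param kind Label stored in the result.
#' @return An `alignment_test` object with `rho`, `p_value`, the two unit
#'   vectors, `n_perm` and `seed`.
#' @export
alignment_test <- function(X, reference, which = c("min", "max"),
                           n_perm = 10000, seed = NULL, kind = "P") {
  which <- match.arg(which)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be complete and numeric", call. = FALSE)
  reference <- as.numeric(reference)
  reference <- reference / sqrt(sum(reference^2))

  S <- stats::cov(X)
  tr <- sum(diag(S))
  if (tr <= 0 ||
      min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-12 * tr) {
    stop("degenerate covariance matrix: rows carry no ", ncol(X),
         "-dimensional variation", call. = FALSE)
  }
  target <- suppressWarnings(min_eigenvector(S, which))
  rho_obs <- vector_correlation(reference, target)

  n <- nrow(X)
  count <- 0L
  for (b in seq_len(n_perm)) {
    Xp <- apply(X, 2, sample)
    vp <- suppressWarnings(min_eigenvector(stats::cov(Xp), which))
    if (abs(sum(vp * reference)) >= rho_obs - 1e-15) count <- count + 1L
  }
  .alignment_result(rho_obs, (1 + count) / (n_perm + 1), reference, target,
                    n_perm, seed, kind)
}

#' @describeIn alignment_test Alignment test on taxon means: rows are the
#'   mean-standardized taxon mean vectors, so the covariance under test is
#'   the divergence matrix **D**.
#' @inheritParams d_matrix
#' @export
taxon_alignment_test <- function(taxa, reference,
                                 traits = c("PN", "MD", "ML"),
                                 ref_means = "P. americana americana",
                                 which = c("min", "max"), n_perm = 10000,
                                 seed = NULL) {
  M <- taxon_mean_matrix(taxa, traits, reference = ref_means)
  alignment_test(M, reference, which = which, n_perm = n_perm, seed = seed,
                 kind = "D")
}
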