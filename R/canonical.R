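.fix_sign <- function(v) {
  nz <- which(abs(v) > 1e-12)
  if (length(nz) > 0 && v[nz[1]] < 0) -v else v
}

#' Canonical analysis of the nonlinear selection surface
#'
#' Diagonalizes the gamma matrix. The canonical axes \eqn{m_i} (unit
#' eigenvectors) describe the principal curvatures of the fitness surface:
#' eigenvalues \eqn{\lambda_i} (sorted descending) give the strength and sign
#' of curvature, and \eqn{\theta_i = m_i \cdot \beta} is the directional
#' gradient along each axis. The axis with the most negative eigenvalue
#' (`m_max`) is the direction of strongest stabilizing selection. Signs are
#' fixed so the first nonzero loading of each axis is positive.
#'
#' @param gamma A `selection_gradients` object or a symmetric p x p matrix.
#' @param beta Optional linear-gradient vector (taken from the
#'   `selection_gradients` object if supplied there).
#' @return An object of class `canonical_axes`: `m` (p x p matrix of axes in
#'   columns, descending lambda), `lambda`, `theta`, `m_max_index`, and the
#'   input matrices. [tidy()] gives one row per axis.
#' @examples
#' ca <- canonical_analysis(phymata_gamma(), phymata_beta())
#' tidy(ca)
#' @export
canonical_analysis <- function(gamma, beta = NULL) {
  if (inherits(gamma, "selection_gradients")) {
    if (is.null(beta)) beta <- gamma$beta
    gamma <- gamma$gamma
  }
  gamma <- as.matrix(gamma)
  if (!isSymmetric(unname(gamma), tol = 1e-8)) {
    stop("gamma must be symmetric", call. = FALSE)
  }
  p <- ncol(gamma)
  e <- eigen((gamma + t(gamma)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  lambda <- e$values[ord]
  m <- apply(e$vectors[, ord, drop = FALSE], 2, .fix_sign)
  rownames(m) <- colnames(gamma) %||% paste0("z", seq_len(p))
  colnames(m) <- paste0("m", seq_len(p))
  theta <- if (is.null(beta)) rep(NA_real_, p) else
    as.vector(crossprod(m, as.numeric(beta)))
  neg <- which(lambda < 0)
  m_max_index <- if (length(neg) > 0) neg[which.max(abs(lambda[neg]))]
                 else NA_integer_
  structure(list(m = m, lambda = lambda, theta = theta,
                 m_max_index = m_max_index, gamma = gamma, beta = beta),
            class = "canonical_axes")
}

#' @export
print.canonical_axes <- function(x, ...) {
  cat("<canonical_axes>\n")
  print(tidy(x), n = Inf)
  if (!is.na(x$m_max_index)) {
    cat("m_max = m", x$m_max_index, " (strongest stabilizing selection)\n",
        sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.canonical_axes <- function(x, ...) {
  p <- length(x$lambda)
  load <- tibble::as_tibble(t(x$m), .name_repair = "minimal")
  names(load) <- rownames(x$m)
  dplyr::bind_cols(
    tibble::tibble(axis = colnames(x$m), theta = x$theta, lambda = x$lambda),
    load)
}

#' Direction of strongest stabilizing selection
#'
#' @param x A `canonical_axes` object.
#' @return The unit eigenvector with the largest-magnitude negative
#'   eigenvalue, or an error if no eigenvalue is negative.
#' @export
m_max <- function(x) {
  stopifnot(inherits(x, "canonical_axes"))
  if (is.na(x$m_max_index)) {
    stop("no negative eigenvalue: surface has no stabilizing direction",
         call. = FALSE)
  }
  x$m[, x$m_max_index]
}

#' Permutation test for canonical eigenvalues
#'
#' Tests the curvature along each canonical axis by permuting fitness across
#' individuals (the multivariate phenotype distribution is held fixed),
#' re-estimating gamma, re-diagonalizing, and comparing the observed
#' eigenvalue of each rank with the null distribution of the same rank
#' (eigenvalues sorted descending in every permutation). By default the test
#' is one-tailed in the direction of the observed sign; p-values use the
#' add-one estimator \eqn{(1 + b) / (n_{perm} + 1)}.
#'
#' @inheritParams selection_gradients
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @param two_tailed If `TRUE`, count permuted eigenvalues as extreme on
#'   absolute value instead of in the observed sign direction.
#' @return A tibble with one row per axis: `axis`, `lambda`, `p.value`,
#'   plus attributes `n_perm` and `seed`.
#' @export
eigenvalue_permutation_test <- function(data, traits = c("PN", "MD", "ML"),
                                        fitness = "fitness", n_perm = 1000,
                                        seed = NULL, double_quadratic = TRUE,
                                        two_tailed = FALSE) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  data <- standardize_traits(data, traits, "variance")
  Z <- trait_matrix(data, traits)
  w <- relative_fitness(data[[fitness]][stats::complete.cases(
    as.data.frame(data)[, traits, drop = FALSE])])
  p <- ncol(Z)
  X <- cbind(1, .quad_design(Z))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient quadratic design", call. = FALSE)
  fac <- if (double_quadratic) 2 else 1

  gamma_eigs <- function(wv) {
    cf <- qr.coef(qrX, wv)[-1]
    G <- matrix(0, p, p)
    diag(G) <- fac * cf[p + seq_len(p)]
    if (p >= 2) {
      idx <- utils::combn(p, 2)
      for (k in seq_len(ncol(idx))) {
        G[idx[1, k], idx[2, k]] <- G[idx[2, k], idx[1, k]] <- cf[2 * p + k]
      }
    }
    sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  }

  obs <- gamma_eigs(w)
  nulls <- matrix(NA_real_, n_perm, p)
  for (b in seq_len(n_perm)) nulls[b, ] <- gamma_eigs(sample(w))

  count <- vapply(seq_len(p), function(r) {
    if (two_tailed) sum(abs(nulls[, r]) >= abs(obs[r]))
    else if (obs[r] >= 0) sum(nulls[, r] >= obs[r])
    else sum(nulls[, r] <= obs[r])
  }, numeric(1))
  out <- tibble::tibble(axis = paste0("m", seq_len(p)), lambda = obs,
                        p.value = (1 + count) / (n_perm + 1))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  out
}
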