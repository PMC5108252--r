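#' Common eigenvectors of several covariance matrices (FG algorithm)
#'
#' Flury-Gautschi iteration: starting from the eigenvectors of the pooled
#' matrix, sweeps over all column pairs of the rotation B, solving each 2 x 2
#' subproblem (a Jacobi-style rotation satisfying the common-principal-
#' components likelihood equations) until successive rotations change by less
#' than `tol`. The returned B maximizes the CPC likelihood in which every
#' group shares the eigenvectors B but keeps its own eigenvalues
#' `diag(t(B) %*% S_i %*% B)`.
#'
#' @param S_list List of symmetric positive-definite p x p matrices.
#' @param n_list Numeric vector of weights (effective sample sizes).
#' @param tol Convergence tolerance on the rotation update.
#' @param max_iter Maximum number of full sweeps.
#' @return Orthonormal p x p matrix B (columns ordered by pooled eigenvalue,
#'   descending; first nonzero loading positive).
#' @export
fg_common_eigenvectors <- function(S_list, n_list, tol = 1e-10,
                                   max_iter = 1000) {
  k <- length(S_list)
  stopifnot(k >= 2, length(n_list) == k)
  p <- ncol(S_list[[1]])
  for (S in S_list) {
    if (!isSymmetric(unname(S), tol = 1e-8)) {
      stop("matrices must be symmetric", call. = FALSE)
    }
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("matrices must be positive definite", call. = FALSE)
    }
  }
  pooled <- Reduce(`+`, Map(`*`, S_list, n_list)) / sum(n_list)
  B <- eigen(pooled, symmetric = TRUE)$vectors

  for (iter in seq_len(max_iter)) {
    B_old <- B
    for (j in seq_len(p - 1)) {
      for (l in (j + 1):p) {
        H <- B[, c(j, l), drop = FALSE]
        Tm <- lapply(S_list, function(S) crossprod(H, S %*% H))
        Q <- diag(2)
        for (inner in 1:50) {
          d1 <- vapply(Tm, function(Tk)
            drop(crossprod(Q[, 1], Tk %*% Q[, 1])), numeric(1))
          d2 <- vapply(Tm, function(Tk)
            drop(crossprod(Q[, 2], Tk %*% Q[, 2])), numeric(1))
          W <- matrix(0, 2, 2)
          for (i in seq_len(k)) {
            W <- W + n_list[i] * (d1[i] - d2[i]) / (d1[i] * d2[i]) * Tm[[i]]
          }
          ev <- eigen((W + t(W)) / 2, symmetric = TRUE)$vectors
          # keep the assignment closest to the current Q (minimal rotation)
          if (abs(ev[1, 1]) < abs(ev[1, 2])) ev <- ev[, 2:1]
          if (ev[1, 1] < 0) ev[, 1] <- -ev[, 1]
          if (ev[2, 2] < 0) ev[, 2] <- -ev[, 2]
          if (max(abs(ev - Q)) < tol) { Q <- ev; break }
          Q <- ev
        }
        B[, c(j, l)] <- H %*% Q
      }
    }
    # sign-align before measuring the update
    flip <- sign(colSums(B * B_old))
    flip[flip == 0] <- 1
    if (max(abs(sweep(B, 2, flip, "*") - B_old)) < tol) break
    if (iter == max_iter) {
      stop("FG algorithm did not converge in ", max_iter,
           " sweeps (last update ",
           format(max(abs(sweep(B, 2, flip, "*") - B_old)), digits = 3), ")",
           call. = FALSE)
    }
  }
  lam <- diag(crossprod(B, pooled %*% B))
  B <- B[, order(lam, decreasing = TRUE), drop = FALSE]
  B <- apply(B, 2, .fix_sign)
  rownames(B) <- colnames(S_list[[1]])
  colnames(B) <- paste0("cpc", seq_len(p))
  B
}

.logdet <- function(S) determinant(S, logarithm = TRUE)$modulus[1]

.orth_complement <- function(b) {
  p <- length(b)
  qr.Q(qr(cbind(b, diag(p))))[, 2:p, drop = FALSE]
}

# -2 log likelihood-ratio of the "one shared eigenvector b" model vs unrelated
.cpc1_chi2 <- function(b, S_list, n_list) {
  b <- b / sqrt(sum(b^2))
  Cb <- .orth_complement(b)
  sum(vapply(seq_along(S_list), function(i) {
    S <- S_list[[i]]
    n_list[i] * (log(drop(crossprod(b, S %*% b))) +
                   .logdet(crossprod(Cb, S %*% Cb)) - .logdet(S))
  }, numeric(1)))
}

.sphere_angles <- function(v) {
  # unit vector -> p-1 spherical angles (p = 3 handled generally)
  v <- v / sqrt(sum(v^2))
  p <- length(v)
  ang <- numeric(p - 1)
  r <- 1
  for (i in seq_len(p - 1)) {
    ang[i] <- acos(max(-1, min(1, v[i] / r)))
    r <- r * sin(ang[i])
    if (r < 1e-12) { ang[(i + 1):(p - 1)] <- 0; break }
  }
  ang[p - 1] <- atan2(v[p], v[p - 1])
  ang
}

.angles_to_vec <- function(ang) {
  p <- length(ang) + 1
  v <- numeric(p)
  r <- 1
  for (i in seq_len(p - 2)) {
    v[i] <- r * cos(ang[i])
    r <- r * sin(ang[i])
  }
  v[p - 1] <- r * cos(ang[p - 1])
  v[p] <- r * sin(ang[p - 1])
  v
}

.fit_proportional <- function(S_list, n_list, tol = 1e-12, max_iter = 500) {
  k <- length(S_list)
  p <- ncol(S_list[[1]])
  rho <- rep(1, k)
  N <- sum(n_list)
  for (it in seq_len(max_iter)) {
    Sigma <- Reduce(`+`, Map(function(S, n, r) n / r * S,
                             S_list, n_list, rho)) / N
    Sinv <- solve(Sigma)
    rho_new <- vapply(S_list, function(S) sum(Sinv * t(S)) / p, numeric(1))
    rho_new <- rho_new / rho_new[1]
    if (max(abs(rho_new - rho)) < tol) { rho <- rho_new; break }
    rho <- rho_new
  }
  Sigma <- Reduce(`+`, Map(function(S, n, r) n / r * S,
                           S_list, n_list, rho)) / N
  chi2 <- sum(vapply(seq_len(k), function(i) {
    n_list[i] * (.logdet(rho[i] * Sigma) - .logdet(S_list[[i]]))
  }, numeric(1)))
  list(chi2 = chi2, rho = rho, Sigma = Sigma)
}

#' Flury hierarchy of covariance-matrix similarity
#'
#' Fits the nested hierarchy equality > proportionality > common principal
#' components (CPC) > partial CPC with one shared component (CPC1) >
#' unrelated, for two groups, and reports for each model the jump-up
#' likelihood-ratio chi-square (model vs unrelated), the step chi-square
#' (model vs the next model down, i.e. the difference of adjacent jump-up
#' statistics), degrees of freedom, the chi-square p-value of the jump-up
#' test, and an AIC computed as jump-up chi-square plus twice the number of
#' free parameters relative to equality.
#'
#' Likelihoods use effective sample sizes \eqn{n_i = N_i - 1}. The equality
#' statistic is \eqn{\sum_i n_i \ln(\det \bar S / \det S_i)} with
#' \eqn{\bar S = \sum_i n_i S_i / \sum_i n_i}; proportionality and CPC
#' statistics come from the corresponding maximum-likelihood estimators
#' (fixed-point iteration and the FG algorithm); the CPC1 shared direction is
#' found by direct likelihood optimization over the unit sphere, started from
#' each full-CPC component.
#'
#' @param S1,S2 Symmetric positive-definite matrices (or [new_trait_cov()]
#'   objects, whose sample sizes are used when `n1`/`n2` are missing).
#' @param n1,n2 Numbers of sampled units (individuals or taxa) behind each
#'   matrix.
#' @return A tibble of class `cpc_fit` with columns `model`, `chi2_step`,
#'   `df_step`, `chi2_jumpup`, `df_jumpup`, `p_jumpup`, `aic`; attributes
#'   `rotation` (the CPC eigenvector matrix) and `proportionality_constant`.
#' @examples
#' flury_hierarchy(phymata_P(), 108, phymata_D(), 37)
#' @export
flury_hierarchy <- function(S1, n1 = NULL, S2 = NULL, n2 = NULL) {
  if (inherits(S1, "trait_cov")) { n1 <- n1 %||% S1$n; S1 <- S1$matrix }
  if (inherits(S2, "trait_cov")) { n2 <- n2 %||% S2$n; S2 <- S2$matrix }
  S_list <- list(as.matrix(S1), as.matrix(S2))
  p <- ncol(S_list[[1]])
  stopifnot(ncol(S_list[[2]]) == p, n1 > p + 1, n2 > p + 1)
  n_list <- c(n1, n2) - 1  # effective sample sizes
  for (S in S_list) {
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("singular or non-positive-definite matrix", call. = FALSE)
    }
  }
  k <- 2
  N <- sum(n_list)

  # equality
  Sbar <- Reduce(`+`, Map(`*`, S_list, n_list)) / N
  chi2_eq <- sum(vapply(seq_len(k), function(i)
    n_list[i] * (.logdet(Sbar) - .logdet(S_list[[i]])), numeric(1)))

  # proportionality
  prop <- .fit_proportional(S_list, n_list)

  # full CPC
  B <- fg_common_eigenvectors(S_list, n_list)
  chi2_cpc <- sum(vapply(seq_len(k), function(i) {
    lam <- diag(crossprod(B, S_list[[i]] %*% B))
    n_list[i] * (sum(log(lam)) - .logdet(S_list[[i]]))
  }, numeric(1)))

  # CPC1: one shared component, optimized over the sphere from each CPC axis
  cands <- lapply(seq_len(p), function(j) {
    opt <- stats::optim(.sphere_angles(B[, j]), function(a)
      .cpc1_chi2(.angles_to_vec(a), S_list, n_list),
      method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 2000))
    opt
  })
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "value"))]]
  chi2_cpc1 <- max(best$value, 0)
  b_shared <- .fix_sign(.angles_to_vec(best$par))

  df_eq <- (k - 1) * p * (p + 1) / 2
  models <- c("equality", "proportionality", "cpc", "cpc1", "unrelated")
  chi2_jumpup <- c(chi2_eq, prop$chi2, chi2_cpc, chi2_cpc1, 0)
  df_jumpup <- c(df_eq,
                 (k - 1) * (p * (p + 1) / 2 - 1),
                 (k - 1) * p * (p - 1) / 2,
                 (k - 1) * (p - 1),
                 0)
  chi2_step <- c(chi2_jumpup[-5] - chi2_jumpup[-1], NA)
  df_step <- c(df_jumpup[-5] - df_jumpup[-1], NA)
  p_jumpup <- c(stats::pchisq(chi2_jumpup[-5], df_jumpup[-5],
                              lower.tail = FALSE), NA)
  aic <- chi2_jumpup + 2 * (df_eq - df_jumpup)

  out <- tibble::tibble(model = models, chi2_step = chi2_step,
                        df_step = df_step, chi2_jumpup = chi2_jumpup,
                        df_jumpup = df_jumpup, p_jumpup = p_jumpup, aic = aic)
  class(out) <- c("cpc_fit", class(out))
  attr(out, "rotation") <- B
  attr(out, "shared_component") <- b_shared
  attr(out, "proportionality_constant") <- prop$rho[2]
  attr(out, "n") <- c(n1, n2)
  out
}

#' Select the best-supported model of matrix similarity
#'
#' `"model_building_aic"` returns the model with the lowest AIC.
#' `"jump_up"` walks the hierarchy from the most constrained model (equality)
#' downward and returns the first model whose jump-up test against
#' "unrelated" is not rejected at `alpha`; if every model is rejected,
#' "unrelated" is returned.
#'
#' @param fits A `cpc_fit` tibble from [flury_hierarchy()].
#' @param method `"model_building_aic"` or `"jump_up"`.
#' @param alpha Rejection level for the jump-up rule.
#' @return Model name (character scalar).
#' @export
best_model <- function(fits, method = c("model_building_aic", "jump_up"),
                       alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(fits, "cpc_fit"))
  if (method == "model_building_aic") {
    return(fits$model[which.min(fits$aic)])
  }
  hier <- fits[fits$model != "unrelated", ]
  ok <- which(hier$p_jumpup >= alpha)
  if (length(ok) == 0) "unrelated" else hier$model[ok[1]]
}

#' @exportS3Method ggplot2::autoplot
autoplot.cpc_fit <- function(object, ...) {
  d <- object[!is.na(object$aic), ]
  d$model <- factor(d$model, levels = d$model)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$aic)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "AIC",
                  title = "Flury hierarchy: model support") +
    ggplot2::theme_minimal()
}
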