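#' Relative fitness
#'
#' Divides absolute fitness (e.g. mating-success counts) by its sample mean,
#' the Lande-Arnold convention, so that regression coefficients are selection
#' gradients. The result has mean exactly 1.
#'
#' @param w Non-negative numeric vector of absolute fitness.
#' @return Numeric vector of relative fitness.
#' @examples
#' relative_fitness(c(2, 4, 6))
#' @export
relative_fitness <- function(w) {
  if (any(w < 0)) stop("fitness must be non-negative", call. = FALSE)
  m <- mean(w)
  if (!is.finite(m) || m <= 0) {
    stop("mean fitness is zero; at least one individual must have positive fitness",
         call. = FALSE)
  }
  w / m
}

.quad_design <- function(Z) {
  p <- ncol(Z)
  tr <- colnames(Z)
  sq <- Z^2
  colnames(sq) <- paste0(tr, "^2")
  cp <- NULL
  if (p >= 2) {
    idx <- utils::combn(p, 2)
    cp <- Z[, idx[1, ], drop = FALSE] * Z[, idx[2, ], drop = FALSE]
    colnames(cp) <- paste0(tr[idx[1, ]], ":", tr[idx[2, ]])
  }
  cbind(Z, sq, cp)
}

#' Linear and nonlinear selection gradients
#'
#' Lande-Arnold multiple-regression estimates of directional (beta) and
#' quadratic/correlational (gamma) selection gradients. Two ordinary
#' least-squares models are fitted to relative fitness: a linear-only model,
#' from which beta and its statistics are reported, and a full quadratic
#' model (linear + squared + pairwise-product terms) supplying gamma. By
#' default the squared-term coefficients are doubled so that the diagonal of
#' gamma is the curvature \eqn{\partial^2 w / \partial z_i^2} of the fitness
#' surface (the Stinchcombe et al. correction); set
#' `double_quadratic = FALSE` for the raw regression coefficients.
#'
#' @param data Data frame of individuals.
#' @param traits Trait column names.
#' @param fitness Name of the absolute-fitness column.
#' @param standardize If `TRUE` (default), variance-standardize the traits
#'   first; if `FALSE` the columns are used as given and are expected to be
#'   already standardized.
#' @param double_quadratic Double the squared-term coefficients (default
#'   `TRUE`).
#' @return An object of class `selection_gradients`: beta and gamma with
#'   standard errors, the two `lm` fits, fit statistics and scale metadata.
#'   Use [tidy()] for a term-level tibble and [glance()] for model-level
#'   statistics.
#' @examples
#' set.seed(1)
#' d <- simulate_selection_sample(sim_config(n_individuals = 300,
#'                                           fitness_model = "quadratic_exact",
#'                                           fitness_noise = "none"))
#' g <- selection_gradients(d, fitness = "fitness")
#' tidy(g)
#' @export
selection_gradients <- function(data, traits = c("PN", "MD", "ML"),
                                fitness = "fitness", standardize = TRUE,
                                double_quadratic = TRUE) {
  if (!fitness %in% names(data)) {
    stop("fitness column '", fitness, "' not found", call. = FALSE)
  }
  if (standardize) data <- standardize_traits(data, traits, "variance")
  Z <- trait_matrix(data, traits)
  p <- ncol(Z)
  n <- nrow(Z)
  w <- relative_fitness(data[[fitness]][stats::complete.cases(
    as.data.frame(data)[, traits, drop = FALSE])])
  if (n <= p + 1) stop("need n > p + 1 individuals", call. = FALSE)
  n_min <- p * (p + 3) / 2 + 1
  if (n <= n_min) {
    stop("nonlinear model needs n > ", n_min, " individuals (have ", n, ")",
         call. = FALSE)
  }

  lin <- stats::lm(w ~ Z)
  if (lin$rank < p + 1) stop("rank-deficient design", call. = FALSE)
  cs <- summary(lin)$coefficients
  beta <- cs[-1, 1]
  beta_se <- cs[-1, 2]
  names(beta) <- names(beta_se) <- colnames(Z)

  X <- .quad_design(Z)
  full <- stats::lm(w ~ X)
  if (full$rank < ncol(X) + 1) stop("rank-deficient quadratic design",
                                    call. = FALSE)
  cf <- summary(full)$coefficients
  est <- cf[-1, 1]
  se <- cf[-1, 2]
  names(est) <- names(se) <- colnames(X)

  gamma <- gamma_se <- matrix(0, p, p, dimnames = list(colnames(Z), colnames(Z)))
  fac <- if (double_quadratic) 2 else 1
  diag(gamma) <- fac * est[p + seq_len(p)]
  diag(gamma_se) <- fac * se[p + seq_len(p)]
  if (p >= 2) {
    idx <- utils::combn(p, 2)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      gamma[i, j] <- gamma[j, i] <- est[2 * p + k]
      gamma_se[i, j] <- gamma_se[j, i] <- se[2 * p + k]
    }
  }

  fstat <- function(fit) {
    s <- summary(fit)
    f <- s$fstatistic %||% c(value = NA, numdf = NA, dendf = NA)
    tibble::tibble(r.squared = s$r.squared, statistic = unname(f[1]),
                   df1 = unname(f[2]), df2 = unname(f[3]),
                   p.value = if (is.na(f[1])) NA_real_ else
                     stats::pf(f[1], f[2], f[3], lower.tail = FALSE))
  }

  structure(list(beta = beta, beta_se = beta_se,
                 gamma = gamma, gamma_se = gamma_se,
                 fit_linear = lin, fit_full = full,
                 stats_linear = fstat(lin), stats_full = fstat(full),
                 scale_tag = if (standardize) "variance_standardized"
                             else "as_given",
                 doubling_applied = double_quadratic,
                 traits = colnames(Z), n = n),
            class = "selection_gradients")
}

#' @export
print.selection_gradients <- function(x, ...) {
  cat(sprintf("<selection_gradients: %d traits, n = %d, scale = %s>\n",
              length(x$beta), x$n, x$scale_tag))
  cat("beta:\n"); print(round(x$beta, 4))
  cat("gamma:\n"); print(round(x$gamma, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.selection_gradients <- function(x, ...) {
  p <- length(x$beta)
  lin <- tibble::tibble(term = x$traits, type = "linear",
                        estimate = unname(x$beta), std.error = unname(x$beta_se))
  ut <- which(upper.tri(x$gamma, diag = TRUE), arr.ind = TRUE)
  quad <- tibble::tibble(
    term = ifelse(ut[, 1] == ut[, 2], paste0(x$traits[ut[, 1]], "^2"),
                  paste0(x$traits[ut[, 1]], ":", x$traits[ut[, 2]])),
    type = ifelse(ut[, 1] == ut[, 2], "quadratic", "correlational"),
    estimate = x$gamma[ut], std.error = x$gamma_se[ut])
  dplyr::bind_rows(lin, quad)
}

#' @exportS3Method generics::glance
glance.selection_gradients <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(model = c("linear", "nonlinear")),
                   dplyr::bind_rows(x$stats_linear, x$stats_full),
                   tibble::tibble(n = x$n))
}

#' Convert variance-standardized gradients to mean-standardized ones
#'
#' With per-trait coefficients of variation \eqn{CV_i = sd_i / mean_i},
#' mean-standardized gradients are \eqn{\beta_{\mu,i} = \beta_{\sigma,i} /
#' CV_i} and \eqn{\gamma_{\mu,ij} = \gamma_{\sigma,ij} / (CV_i CV_j)}.
#'
#' @param g A `selection_gradients` object (variance-standardized).
#' @param means,sds Named numeric vectors of trait means and SDs on the
#'   original measurement scale.
#' @return A `selection_gradients` object on the mean-standardized scale.
#' @export
mean_standardize_gradients <- function(g, means, sds) {
  stopifnot(inherits(g, "selection_gradients"))
  means <- means[g$traits]; sds <- sds[g$traits]
  if (any(!is.finite(means)) || any(!is.finite(sds)) ||
      any(means <= 0) || any(sds <= 0)) {
    stop("means and sds must be positive for all traits", call. = FALSE)
  }
  cv <- sds / means
  out <- g
  out$beta <- g$beta / cv
  out$beta_se <- g$beta_se / cv
  cc <- tcrossprod(cv)
  out$gamma <- g$gamma / cc
  out$gamma_se <- g$gamma_se / cc
  out$scale_tag <- "mean_standardized"
  out
}
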