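.random_unit <- function(p) {
  v <- stats::rnorm(p)
  v / sqrt(sum(v^2))
}

.cv_dev_explained <- function(x, y, lambda) {
  # LOO-CV explained deviance of a cubic smoothing spline at fixed lambda
  fit <- try(suppressWarnings(
    stats::smooth.spline(x, y, lambda = lambda, cv = TRUE,
                         keep.data = FALSE)), silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$cv.crit)) return(-Inf)
  1 - fit$cv.crit / mean((y - mean(y))^2)
}

#' Dominant surface direction by projection pursuit
#'
#' Searches for the unit direction `a` in trait space along which a cubic
#' smoothing spline of relative fitness on the scalar projection `Z a`
#' explains the most leave-one-out cross-validated deviance. Candidate
#' directions are drawn uniformly on the sphere (`n_starts` of them); each is
#' scored across a grid of log-scale smoothing parameters (the spline is fit
#' with smoothing parameter `exp(lambda)` for each grid value `lambda`), and
#' the best candidate is refined by Nelder-Mead ascent on the sphere. Because
#' a projection and its negative define the same axis, the result is
#' sign-normalized (first nonzero loading positive).
#'
#' This estimator does not rely on the quadratic-regression gamma and so
#' offers an independent check on the canonical `m_max`: a strongly convex
#' surface direction found here should align with it.
#'
#' @inheritParams selection_gradients
#' @param n_starts Number of random starting directions (default 5000).
#' @param lambda_grid Grid of log smoothing parameters (default -10 to 10 in
#'   steps of 2).
#' @param seed Optional integer seed.
#' @param refine Refine the best random start by local optimization.
#' @return An object of class `pp_direction`: `direction` (unit vector),
#'   `cv_deviance`, `lambda_best` (log smoothing parameter at the optimum),
#'   and `stability`, a tibble of the best direction found at each grid value
#'   with its correlation to the overall winner.
#' @export
projection_pursuit <- function(data, traits = c("PN", "MD", "ML"),
                               fitness = "fitness", n_starts = 5000,
                               lambda_grid = seq(-10, 10, by = 2),
                               seed = NULL, refine = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  data <- standardize_traits(data, traits, "variance")
  Z <- trait_matrix(data, traits)
  w <- relative_fitness(data[[fitness]][stats::complete.cases(
    as.data.frame(data)[, traits, drop = FALSE])])
  n <- nrow(Z); p <- ncol(Z)
  if (n < 10) stop("too few individuals for spline smoothing", call. = FALSE)

  best_per_lambda <- vector("list", length(lambda_grid))
  score_per_lambda <- rep(-Inf, length(lambda_grid))
  for (s in seq_len(n_starts)) {
    a <- .random_unit(p)
    x <- drop(Z %*% a)
    for (li in seq_along(lambda_grid)) {
      sc <- .cv_dev_explained(x, w, exp(lambda_grid[li]))
      if (sc > score_per_lambda[li]) {
        score_per_lambda[li] <- sc
        best_per_lambda[[li]] <- a
      }
    }
  }
  li_best <- which.max(score_per_lambda)
  a_best <- best_per_lambda[[li_best]]
  score <- score_per_lambda[li_best]

  if (refine) {
    opt <- stats::optim(.sphere_angles(a_best), function(ang) {
      a <- .angles_to_vec(ang)
      -.cv_dev_explained(drop(Z %*% a), w, exp(lambda_grid[li_best]))
    }, method = "Nelder-Mead", control = list(reltol = 1e-10, maxit = 500))
    if (is.finite(opt$value) && -opt$value > score) {
      a_best <- .angles_to_vec(opt$par)
      score <- -opt$value
    }
  }
  a_best <- .fix_sign(a_best / sqrt(sum(a_best^2)))
  names(a_best) <- colnames(Z)

  stability <- tibble::tibble(
    log_lambda = lambda_grid,
    cv_deviance = score_per_lambda,
    correlation_with_best = vapply(best_per_lambda, function(a)
      if (is.null(a)) NA_real_ else vector_correlation(a, a_best), numeric(1)))

  structure(list(direction = a_best, cv_deviance = score,
                 lambda_best = lambda_grid[li_best], stability = stability,
                 n_starts = n_starts, seed = seed),
            class = "pp_direction")
}

#' @export
print.pp_direction <- function(x, ...) {
  cat(sprintf(
    "<pp_direction> CV deviance %.3f at log-lambda %g (%d starts)\n",
    x$cv_deviance, x$lambda_best, x$n_starts))
  print(round(x$direction, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pp_direction <- function(x, ...) {
  tibble::tibble(trait = names(x$direction), loading = unname(x$direction))
}
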