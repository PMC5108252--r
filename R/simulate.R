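.default_P_raw <- function() {
  # raw-scale phenotypic covariance implied by the published mean-standardized
  # P-matrix and the reference trait means: cov_ij = P_ms[i,j] * mean_i * mean_j
  means <- phymata_reference_means()
  phymata_P(se = FALSE)$matrix * tcrossprod(means)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' emulate the study conditions the analyses were designed for: a field
#' sample of 44 males scored for mating success under a surface with the
#' published gradient structure, two common-garden rearing samples of 50 and
#' 58 males for **P**, and 37 taxa whose means scatter around a grand mean
#' with covariance equal to the published divergence matrix. Phenotypes are
#' multivariate normal on the raw measurement scale, with covariance implied
#' by the published mean-standardized **P** and the reference trait means.
#'
#' @param seed Unused here (pass `seed` to the generators); kept for
#'   completeness when serializing a configuration.
#' @param n_individuals Field-sample size for the selection study.
#' @param trait_means Raw-scale trait means (PN mm; MD, ML darkness units).
#' @param P_true Raw-scale phenotypic covariance.
#' @param fitness_model `"quadratic_exact"` (expected fitness
#'   \eqn{\max(0, 1 + \beta' z + z' \gamma z / 2)} on the variance-
#'   standardized scale) or `"gaussian_surface"` (expected mating probability
#'   \eqn{\propto \exp(-(z - \theta)' \Omega^{-1} (z - \theta) / 2)}).
#' @param beta_true,gamma_true Gradients of the quadratic surface
#'   (variance-standardized scale); defaults are the published estimates.
#' @param optimum,width_matrix Gaussian-surface optimum and width
#'   (variance-standardized scale).
#' @param base_rate Peak mating probability for the Bernoulli realization.
#' @param fitness_noise `"none"`, `"poisson"`, or `"bernoulli"` (default:
#'   mated / not mated, matching a mating-success study).
#' @param n_taxa Number of taxa for the divergence generator.
#' @param grand_mean Raw-scale grand mean of taxon means.
#' @param D_true Raw-scale between-taxon covariance of true means; default is
#'   the published **D** rescaled to the raw scale.
#' @param per_taxon_n Integer or length-2 range of specimens per taxon.
#' @param year_n Sample sizes of the two rearing years.
#' @param year_offsets List of two raw-scale mean offsets (year effects).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       n_individuals = 44,
                       trait_means = phymata_reference_means(),
                       P_true = .default_P_raw(),
                       fitness_model = c("gaussian_surface", "quadratic_exact"),
                       beta_true = phymata_beta(),
                       gamma_true = phymata_gamma(),
                       optimum = c(0, 0, 0),
                       width_matrix = diag(2, 3),
                       base_rate = 0.7,
                       fitness_noise = c("bernoulli", "poisson", "none"),
                       n_taxa = 37,
                       grand_mean = trait_means,
                       D_true = phymata_D()$matrix * tcrossprod(trait_means),
                       per_taxon_n = c(4, 20),
                       year_n = c(50, 58),
                       year_offsets = list(rep(0, 3), 0.03 * trait_means)) {
  fitness_model <- match.arg(fitness_model)
  fitness_noise <- match.arg(fitness_noise)
  p <- length(trait_means)
  stopifnot(nrow(P_true) == p, isSymmetric(unname(as.matrix(P_true))),
            nrow(gamma_true) == p, length(beta_true) == p,
            n_individuals > 0, n_taxa > 0)
  if (min(eigen(P_true, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("P_true must be positive definite", call. = FALSE)
  }
  if (min(eigen(D_true, symmetric = TRUE, only.values = TRUE)$values) < 0) {
    stop("D_true must be positive semidefinite", call. = FALSE)
  }
  structure(list(seed = seed, n_individuals = n_individuals,
                 trait_means = trait_means, P_true = as.matrix(P_true),
                 fitness_model = fitness_model, beta_true = beta_true,
                 gamma_true = as.matrix(gamma_true), optimum = optimum,
                 width_matrix = as.matrix(width_matrix),
                 base_rate = base_rate, fitness_noise = fitness_noise,
                 n_taxa = n_taxa, grand_mean = grand_mean,
                 D_true = as.matrix(D_true), per_taxon_n = per_taxon_n,
                 year_n = year_n, year_offsets = year_offsets),
            class = "sim_config")
}

.sim_traits <- function(n, mu, Sigma, traits = c("PN", "MD", "ML")) {
  Z <- matrix(MASS::mvrnorm(n, mu = mu, Sigma = Sigma), nrow = n)
  colnames(Z) <- traits
  Z
}

#' Simulate a selection sample
#'
#' Draws phenotypes from a multivariate normal with the configured mean and
#' covariance, computes expected fitness from the configured surface on the
#' variance-standardized scale, and realizes fitness with the configured
#' noise model (`"bernoulli"` mated/not, `"poisson"` counts, or `"none"` for
#' the exact expectation). Under the quadratic surface, negative expected
#' fitness is truncated at zero (a message reports the count).
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (reproducible given the same value).
#' @return A tibble with `id`, the trait columns, and `fitness`.
#' @export
simulate_selection_sample <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  Z <- .sim_traits(cfg$n_individuals, cfg$trait_means, cfg$P_true)
  Zs <- scale(Z)
  if (cfg$fitness_model == "quadratic_exact") {
    wexp <- 1 + drop(Zs %*% cfg$beta_true) +
      0.5 * rowSums((Zs %*% cfg$gamma_true) * Zs)
    n_neg <- sum(wexp < 0)
    if (n_neg > 0) {
      message("truncating ", n_neg, " negative expected fitness value(s) at 0")
      wexp <- pmax(wexp, 0)
    }
  } else {
    dev <- sweep(Zs, 2, cfg$optimum)
    Oinv <- solve(cfg$width_matrix)
    wexp <- cfg$base_rate * exp(-0.5 * rowSums((dev %*% Oinv) * dev))
  }
  w <- switch(cfg$fitness_noise,
              none = wexp,
              poisson = stats::rpois(length(wexp), wexp),
              bernoulli = stats::rbinom(length(wexp), 1, pmin(wexp, 1)))
  out <- tibble::as_tibble(as.data.frame(Z))
  tibble::add_column(out, id = seq_len(nrow(out)), .before = 1,
                     .name_repair = "minimal") |>
    tibble::add_column(fitness = as.numeric(w))
}

#' Simulate taxon trait summaries
#'
#' True taxon means are drawn from a multivariate normal around the grand
#' mean with covariance `D_true`; each taxon then contributes `n_k`
#' individual draws around its true mean with covariance `P_true`, from
#' which the reported sample means and SDs are computed (so reported means
#' carry within-taxon sampling noise `P_true / n_k`).
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return A tibble shaped like [phymata_taxa()]: `taxon`, `n`,
#'   `<trait>_mean`, `<trait>_sd`.
#' @export
simulate_taxon_means <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  traits <- names(cfg$grand_mean) %||% c("PN", "MD", "ML")
  K <- cfg$n_taxa
  mus <- .sim_traits(K, cfg$grand_mean, cfg$D_true, traits)
  nk <- if (length(cfg$per_taxon_n) == 2 &&
              cfg$per_taxon_n[1] != cfg$per_taxon_n[2]) {
    sample(seq(cfg$per_taxon_n[1], cfg$per_taxon_n[2]), K, replace = TRUE)
  } else rep(cfg$per_taxon_n[1], K)
  rows <- lapply(seq_len(K), function(k) {
    Zk <- .sim_traits(nk[k], mus[k, ], cfg$P_true, traits)
    row <- tibble::tibble(taxon = sprintf("taxon_%03d", k), n = nk[k])
    for (tr in traits) {
      row[[paste0(tr, "_mean")]] <- mean(Zk[, tr])
      row[[paste0(tr, "_sd")]] <- stats::sd(Zk[, tr])
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Simulate a two-year common-garden sample
#'
#' Each year's phenotypes are multivariate normal around
#' `trait_means + year_offset` with the same covariance `P_true`, emulating
#' rearing cohorts whose multivariate means differ (e.g. between years).
#' Pooling the raw rows inflates variance along the offset direction;
#' [p_matrix()] with `pool_by = "year"` removes the offset by within-year
#' mean standardization first.
#'
#' @param cfg A [sim_config()] with two `year_offsets`.
#' @param seed Optional integer seed.
#' @return A tibble with `year` and the trait columns.
#' @export
simulate_two_year_p_sample <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), length(cfg$year_offsets) == 2)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(1:2, function(y) {
    Z <- .sim_traits(cfg$year_n[y], cfg$trait_means + cfg$year_offsets[[y]],
                     cfg$P_true)
    d <- tibble::as_tibble(as.data.frame(Z))
    tibble::add_column(d, year = y, .before = 1)
  })
  dplyr::bind_rows(rows)
}
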