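#' Mahalanobis index of multivariate sexual dimorphism
#'
#' \eqn{d = \sqrt{(\mu_m - \mu_f)' S^{-1} (\mu_m - \mu_f)}}: the
#' covariance-weighted distance between male and female mean phenotypes.
#' Zero iff the sexes share the same mean vector; symmetric in the sexes;
#' scales as \eqn{\sqrt{c}} when `S` is divided by `c`.
#'
#' @param male_means,female_means Numeric trait-mean vectors (mean-
#'   standardized scale recommended so the index is unit-free).
#' @param S Positive-definite covariance matrix (or [new_trait_cov()]).
#' @return Non-negative scalar.
#' @examples
#' mahalanobis_dimorphism(c(1, 0), c(0, 0), diag(c(4, 1)))
#' @export
mahalanobis_dimorphism <- function(male_means, female_means, S) {
  S <- .cov_input(S)
  d <- as.numeric(male_means) - as.numeric(female_means)
  if (length(d) != ncol(S)) stop("dimension mismatch", call. = FALSE)
  Sinv <- try(solve(S), silent = TRUE)
  if (inherits(Sinv, "try-error")) {
    stop("covariance matrix is singular", call. = FALSE)
  }
  sqrt(max(drop(t(d) %*% Sinv %*% d), 0))
}

#' Per-taxon dimorphism table
#'
#' Computes the Mahalanobis dimorphism index for every taxon present in both
#' sexes, from individual-level data, after mean-standardizing traits by
#' their grand means (or by `reference` means). The metric matrix is either
#' the pooled within-taxon, both-sex covariance of the standardized traits
#' (default) or a user-supplied reference covariance.
#'
#' @param data Data frame of individuals with taxon and sex columns.
#' @param traits Trait column names.
#' @param taxon,sex Names of the taxon and sex columns; sex coded so that
#'   `male_level` identifies males.
#' @param male_level Value of the sex column identifying males.
#' @param covariance `"pooled_within_taxon"` or a p x p matrix (or
#'   [new_trait_cov()]) to use as the metric.
#' @param reference Optional named vector of reference trait means for
#'   standardization; default uses the grand means of `data`.
#' @param min_female_n Taxa with fewer females are skipped (with a message).
#' @return A tibble with one row per retained taxon: `taxon`, `d_index`,
#'   male and female standardized means per trait, and sample sizes.
#'   Attribute `"covariance_used"` stores the metric matrix.
#' @export
dimorphism_table <- function(data, traits = c("PN", "MD", "ML"),
                             taxon = "taxon", sex = "sex",
                             male_level = "M",
                             covariance = "pooled_within_taxon",
                             reference = NULL, min_female_n = 2) {
  d <- tibble::as_tibble(data)
  stopifnot(taxon %in% names(d), sex %in% names(d))
  if (is.null(reference)) {
    reference <- vapply(traits, function(tr) mean(d[[tr]], na.rm = TRUE),
                        numeric(1))
  }
  d <- standardize_traits(d, traits, "mean", reference = reference)
  d$.sex <- ifelse(d[[sex]] == male_level, "male", "female")
  d$.taxon <- as.character(d[[taxon]])

  counts <- dplyr::count(d, .data$.taxon, .data$.sex)
  wide <- tidyr::pivot_wider(counts, names_from = ".sex",
                             values_from = "n", values_fill = 0)
  if (!"female" %in% names(wide)) wide$female <- 0
  if (!"male" %in% names(wide)) wide$male <- 0
  keep <- wide$.taxon[wide$male >= 1 & wide$female >= min_female_n]
  skipped <- setdiff(unique(d$.taxon), keep)
  if (length(skipped) > 0) {
    message("skipping ", length(skipped),
            " taxon/taxa without both sexes (females >= ", min_female_n,
            "): ", paste(skipped, collapse = ", "))
  }
  d <- d[d$.taxon %in% keep, , drop = FALSE]
  if (nrow(d) == 0) stop("no taxon has both sexes represented", call. = FALSE)

  if (identical(covariance, "pooled_within_taxon")) {
    Z <- trait_matrix(d, traits)
    grp <- interaction(d$.taxon, d$.sex, drop = TRUE)
    resid <- Z - rowsum(Z, grp)[grp, , drop = FALSE] /
      as.vector(table(grp))[grp]
    S <- crossprod(resid) / (nrow(Z) - nlevels(grp))
  } else {
    S <- .cov_input(covariance)
  }

  per_sex_means <- d |>
    dplyr::group_by(.data$.taxon, .data$.sex) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(traits), mean),
                     n = dplyr::n(), .groups = "drop")

  out <- purrr::map_dfr(sort(unique(d$.taxon)), function(tx) {
    mm <- per_sex_means[per_sex_means$.taxon == tx &
                          per_sex_means$.sex == "male", ]
    ff <- per_sex_means[per_sex_means$.taxon == tx &
                          per_sex_means$.sex == "female", ]
    row <- tibble::tibble(taxon = tx,
                          d_index = mahalanobis_dimorphism(
                            as.numeric(mm[1, traits]),
                            as.numeric(ff[1, traits]), S),
                          n_male = mm$n[1], n_female = ff$n[1])
    for (tr in traits) {
      row[[paste0("male_", tr)]] <- mm[[tr]][1]
      row[[paste0("female_", tr)]] <- ff[[tr]][1]
    }
    row
  })
  attr(out, "covariance_used") <- S
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.pp_direction <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$loading)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "loading",
                  title = "Projection-pursuit surface direction") +
    ggplot2::theme_minimal()
}
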