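#' Run the full concordance analysis
#'
#' Orchestrates the analysis chain: selection gradients and canonical axes
#' (estimated from individual fitness data when supplied, or taken from
#' supplied canonical vectors), the **P**- and **D**-matrices, vector-
#' correlation alignment tests of `m_max` against `p_min` and `d_min`,
#' directional variances along every canonical axis with a random-direction
#' average, and the Flury hierarchy comparing **P** and **D**.
#'
#' Every input can be given at one of two levels: raw rows (from which the
#' matrix is estimated and permutation p-values are available) or a
#' ready-made matrix (alignment is then reported without a permutation
#' p-value, since the null requires row-level reshuffling).
#'
#' @param selection_data Optional individual-level data frame with trait and
#'   fitness columns; used to estimate gradients and `m_max`.
#' @param m_vectors Optional p x p matrix of canonical axes (columns), the
#'   last of which — or the one named `"m_max"` — is the stabilizing
#'   direction. Required if `selection_data` is absent.
#' @param p_data Optional individual-level data frame for **P** (with
#'   `pool_by` column if two-year); alternatively supply `P`.
#' @param P,D Optional [new_trait_cov()] objects (used when raw rows are
#'   unavailable).
#' @param taxa Optional taxon-mean tibble for **D** (enables the divergence
#'   permutation test).
#' @param traits Trait column names.
#' @param reference_means Named vector of reference trait means for the
#'   mean-standardized divergence scale.
#' @param fitness,pool_by Column names in `selection_data` / `p_data`.
#' @param n_perm Permutations for the alignment tests.
#' @param n_random Random directions for the average directional variance.
#' @param seed Integer seed controlling every stochastic step.
#' @return An object of class `analysis_report` (a list): `gradients`,
#'   `canonical`, `P`, `D`, `alignment` (tibble), `e_table` (tibble of
#'   directional variances), `cpc` (Flury table), `provenance`.
#' @export
run_full_pipeline <- function(selection_data = NULL, m_vectors = NULL,
                              p_data = NULL, P = NULL, D = NULL, taxa = NULL,
                              traits = c("PN", "MD", "ML"),
                              reference_means = phymata_reference_means(),
                              fitness = "fitness", pool_by = "year",
                              n_perm = 10000, n_random = 1000, seed = 1L) {
  set.seed(seed)
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  gradients <- canonical <- NULL
  if (!is.null(selection_data)) {
    gradients <- selection_gradients(selection_data, traits, fitness)
    canonical <- canonical_analysis(gradients)
    m_all <- canonical$m
    mmax <- m_max(canonical)
  } else if (!is.null(m_vectors)) {
    m_all <- as.matrix(m_vectors)
    j <- if (!is.null(colnames(m_all)) && "m_max" %in% colnames(m_all)) {
      which(colnames(m_all) == "m_max")
    } else ncol(m_all)
    mmax <- m_all[, j]
  } else {
    stop("supply either 'selection_data' or 'm_vectors'", call. = FALSE)
  }

  if (is.null(P)) {
    if (is.null(p_data)) stop("supply either 'p_data' or 'P'", call. = FALSE)
    pb <- if (!is.null(pool_by) && pool_by %in% names(p_data)) pool_by else NULL
    P <- p_matrix(p_data, traits, pool_by = pb, jackknife = TRUE)
  }
  if (is.null(D)) {
    if (is.null(taxa)) stop("supply either 'taxa' or 'D'", call. = FALSE)
    D <- d_matrix(taxa, traits, reference = reference_means)
  }

  # alignment of m_max with p_min and d_min
  align_rows <- list()
  if (!is.null(p_data)) {
    Xp <- if (!is.null(pool_by) && pool_by %in% names(p_data)) {
      trait_matrix(standardize_traits(p_data, traits, "mean", by = pool_by),
                   traits)
    } else trait_matrix(p_data, traits)
    ap <- alignment_test(Xp, mmax, "min", n_perm = n_perm, kind = "P")
  } else {
    note("P supplied as a matrix: alignment p-value unavailable")
    ap <- .alignment_result(
      vector_correlation(mmax, min_eigenvector(P)), NA_real_,
      mmax / sqrt(sum(mmax^2)), min_eigenvector(P), 0L, seed, "P")
  }
  align_rows$P <- tidy(ap)
  if (!is.null(taxa)) {
    ad <- taxon_alignment_test(taxa, mmax, traits, ref_means = reference_means,
                               n_perm = n_perm)
  } else {
    note("D supplied as a matrix: alignment p-value unavailable")
    ad <- .alignment_result(
      vector_correlation(mmax, min_eigenvector(D)), NA_real_,
      mmax / sqrt(sum(mmax^2)), min_eigenvector(D), 0L, seed, "D")
  }
  align_rows$D <- tidy(ad)
  alignment <- dplyr::bind_rows(align_rows)

  # directional variances along each canonical axis + random average
  axis_names <- colnames(m_all) %||% paste0("m", seq_len(ncol(m_all)))
  e_table <- purrr::map_dfr(seq_len(ncol(m_all)), function(j) {
    tibble::tibble(direction = axis_names[j],
                   e_P = directional_variance(P, m_all[, j]),
                   e_D = directional_variance(D, m_all[, j]))
  })
  rp <- random_direction_average(P, k = n_random)
  rd <- random_direction_average(D, k = n_random)
  e_table <- dplyr::bind_rows(
    e_table, tibble::tibble(direction = "random_average",
                            e_P = rp$mean, e_D = rd$mean))

  cpc <- flury_hierarchy(P, P$n, D, D$n)

  structure(list(gradients = gradients, canonical = canonical,
                 m_vectors = m_all, P = P, D = D, alignment = alignment,
                 e_table = e_table, cpc = cpc,
                 provenance = list(seed = seed, n_perm = n_perm,
                                   n_random = n_random,
                                   traits = traits,
                                   reference_means = reference_means,
                                   package_version =
                                     as.character(utils::packageVersion("selscape"))),
                 warnings = warnings_log),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n\nAlignment of m_max with minimum-variance directions:\n")
  print(x$alignment)
  cat("\nDirectional variances e(m):\n")
  print(x$e_table)
  cat("\nFlury hierarchy (P vs D):\n")
  print(tibble::as_tibble(x$cpc))
  if (length(x$warnings) > 0) {
    cat("\nNotes:\n"); for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}

#' Contour plot of a quadratic fitness surface for two traits
#'
#' Evaluates the best-quadratic approximation \eqn{w = 1 + \beta' z +
#' z' \gamma z / 2} over a grid of two chosen traits (the remaining traits
#' held at zero, i.e. their standardized mean) and draws filled contours with
#' the individuals overlaid.
#'
#' @param gradients A `selection_gradients` object.
#' @param data Optional individual data to overlay (standardized internally).
#' @param traits Length-2 character vector of trait names to display.
#' @param fitness Fitness column in `data` (used for point size).
#' @param grid_n Grid resolution.
#' @return A ggplot object.
#' @export
plot_selection_surface <- function(gradients, data = NULL,
                                   traits = c("MD", "ML"),
                                   fitness = "fitness", grid_n = 60) {
  stopifnot(inherits(gradients, "selection_gradients"), length(traits) == 2)
  all_tr <- gradients$traits
  i <- match(traits, all_tr)
  if (anyNA(i)) stop("traits not found in the gradient object", call. = FALSE)
  r <- seq(-3, 3, length.out = grid_n)
  grid <- expand.grid(x = r, y = r)
  Zg <- matrix(0, nrow(grid), length(all_tr))
  Zg[, i[1]] <- grid$x
  Zg[, i[2]] <- grid$y
  grid$w <- 1 + drop(Zg %*% gradients$beta) +
    0.5 * rowSums((Zg %*% gradients$gamma) * Zg)
  pl <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_contour_filled(ggplot2::aes(z = .data$w), alpha = 0.85) +
    ggplot2::labs(x = paste(traits[1], "(standardized)"),
                  y = paste(traits[2], "(standardized)"),
                  fill = "relative fitness") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    ds <- standardize_traits(data, all_tr, "variance")
    pts <- tibble::tibble(x = ds[[traits[1]]], y = ds[[traits[2]]])
    pl <- pl + ggplot2::geom_point(data = pts, colour = "white", size = 0.8)
  }
  pl
}

#' @exportS3Method ggplot2::autoplot
autoplot.canonical_axes <- function(object, ...) {
  d <- tidy(object)
  d_long <- tidyr::pivot_longer(d, cols = -c("axis", "theta", "lambda"),
                                names_to = "trait", values_to = "loading")
  ggplot2::ggplot(d_long,
                  ggplot2::aes(x = .data$trait, y = .data$loading)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~axis) +
    ggplot2::labs(x = NULL, y = "loading",
                  title = "Canonical axes of the selection surface") +
    ggplot2::theme_minimal()
}
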