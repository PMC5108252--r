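test_that("vector correlation is a sign- and scale-invariant cosine", {
  expect_equal(vector_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(vector_correlation(c(1, 0), c(0, 1)), 0)
  expect_equal(vector_correlation(c(1, 1, 0), c(-3, -3, 0)), 1)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(vector_correlation(a, b), vector_correlation(-2 * a, 5 * b),
               tolerance = 1e-12)
  expect_error(vector_correlation(c(0, 0, 0), a), "zero")
  expect_error(vector_correlation(1:2, 1:3), "length")
})

test_that("published m_max aligns with p_min and d_min as reported", {
  mmax <- phymata_m_vectors()[, "m_max"]
  pmin <- min_eigenvector(phymata_P())
  expect_within(vector_correlation(mmax, pmin), 0.78, 0.01)
  dmin <- min_eigenvector(phymata_D())
  expect_within(vector_correlation(mmax, dmin), 0.82, 0.01)
  # cross-check p_min against the characteristic-polynomial eigensolver
  oracle <- poly_eigen3(phymata_P()$matrix)
  v <- oracle$vectors[, 3]
  expect_equal(vector_correlation(v, pmin), 1, tolerance = 1e-8)
})

test_that("extreme eigenvectors match closed forms and flag degeneracy", {
  expect_equal(unname(min_eigenvector(diag(c(3, 2, 1)))), c(0, 0, 1))
  expect_equal(unname(min_eigenvector(diag(c(3, 2, 1)), "max")), c(1, 0, 0))
  expect_warning(min_eigenvector(diag(3)), "degenerate")
  # min/max eigenvectors of random symmetric 3x3s agree with the brute-force
  # characteristic-polynomial solver
  set.seed(2)
  for (r in 1:20) {
    A <- crossprod(matrix(rnorm(9), 3))
    o <- poly_eigen3(A)
    expect_equal(vector_correlation(min_eigenvector(A), o$vectors[, 3]), 1,
                 tolerance = 1e-8)
    expect_equal(vector_correlation(min_eigenvector(A, "max"),
                                    o$vectors[, 1]), 1, tolerance = 1e-8)
  }
})

test_that("directional variance is the quadratic form, summing to the trace", {
  expect_equal(directional_variance(diag(3), c(0, 1, 0)), 1)
  P <- phymata_P()
  m1 <- phymata_m_vectors()[, "m1"]
  expect_within(directional_variance(P, m1), 0.015, 1e-3)
  expect_equal(directional_variance(P, m1),
               unname(quad_form_loop(m1, P$matrix)), tolerance = 1e-12)
  # over any orthonormal basis, e sums to the trace
  B <- random_rotation(3)
  expect_equal(sum(apply(B, 2, directional_variance, A = P)),
               sum(diag(P$matrix)), tolerance = 1e-10)
  expect_warning(directional_variance(P, c(1, 1, 1)), "unit")
  expect_error(directional_variance(P, c(1, 0)), "dimension")
})

test_that("random-direction average converges to trace/p", {
  expect_equal(random_direction_average(diag(3), k = 50, seed = 1)$mean, 1,
               tolerance = 1e-12)
  r <- random_direction_average(phymata_P(), k = 20000, seed = 2)
  expect_within(r$mean, sum(diag(phymata_P()$matrix)) / 3, 3e-4)
  # the published average for P (printed 0.010) at the published k
  r2 <- random_direction_average(phymata_P(), k = 1000, seed = 3)
  expect_true(r2$mean > 0.0095 && r2$mean < 0.0115)
  expect_error(random_direction_average(diag(3), k = 1), "k must")
})

test_that("alignment permutation test counts correctly and detects planted structure", {
  set.seed(31)
  # the within-trait shuffle preserves marginal variances, so power comes
  # from an oblique low-variance direction (correlation structure): here
  # z3 is nearly determined by z1 + z2
  n <- 100
  z1 <- rnorm(n); z2 <- rnorm(n)
  X <- cbind(z1, z2, (z1 + z2) / 2 + rnorm(n, sd = 0.1))
  ref <- c(1, 1, -2) / sqrt(6) # the planted minimum-variance direction
  res <- alignment_test(X, reference = ref, n_perm = 2000, seed = 1)
  expect_gt(res$rho, 0.95)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$rho,
               vector_correlation(res$reference_vector, res$target_vector),
               tolerance = 1e-12)
  # p floor: n_perm = 99 with observed above all permutations gives 0.01
  expect_equal((1 + 0) / (99 + 1), 0.01)
  expect_gte(res$p_value, 1 / 2001)
  expect_error(alignment_test(X, c(0, 0, 1), n_perm = 0), "n_perm")
  # identical rows: degenerate covariance
  X0 <- matrix(1, 5, 3)
  expect_error(alignment_test(X0, c(0, 0, 1)), "degenerate")
})

test_that("alignment p-values are near-uniform under a spherical null", {
  set.seed(77)
  n_rep <- 200
  pvals <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    X <- matrix(rnorm(40 * 3), 40, 3)
    ref <- rnorm(3)
    pvals[r] <- alignment_test(X, ref, n_perm = 199)$p_value
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # rejection rate at 0.05 compatible with the nominal level
  expect_gt(mean(pvals <= 0.05), 0.02)
  expect_lt(mean(pvals <= 0.05), 0.09)
})

test_that("taxon-mean alignment reproduces the published divergence correlation", {
  res <- taxon_alignment_test(phymata_taxa(), phymata_m_vectors()[, "m_max"],
                              ref_means = phymata_reference_means(),
                              n_perm = 500, seed = 9)
  expect_within(res$rho, 0.82, 0.01)
  # the taxon-mean shuffle preserves marginal divergence, so this null is
  # conservative; the p-value is only required to be a valid probability
  expect_true(res$p_value > 0 && res$p_value <= 1)
  # p-ordering: an aligned reference beats a deliberately misaligned one
  mis <- min_eigenvector(phymata_D(), "max")
  res_mis <- taxon_alignment_test(phymata_taxa(), mis,
                                  ref_means = phymata_reference_means(),
                                  n_perm = 500, seed = 9)
  expect_lt(res$p_value, res_mis$p_value)
  # identical taxa produce a degenerate matrix
  taxa0 <- tibble::tibble(taxon = c("a", "b", "c"), n = 5,
                          PN_mean = 2, MD_mean = 100, ML_mean = 50)
  expect_error(taxon_alignment_test(taxa0, c(0, 0, 1),
                                    ref_means = c(PN = 2, MD = 100, ML = 50)),
               "degenerate")
})
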