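test_that("p_matrix matches a loop covariance oracle and pools correctly", {
  set.seed(4)
  d <- tibble::tibble(PN = rnorm(30, 3, 0.2), MD = rnorm(30, 200, 15),
                      ML = rnorm(30, 150, 30))
  P <- p_matrix(d)
  expect_s3_class(P, "trait_cov")
  expect_equal(unname(P$matrix),
               loop_cov(as.matrix(d[, c("PN", "MD", "ML")])),
               tolerance = 1e-10)
  expect_equal(P$n, 30)

  # two identical groups: pooled (mean-standardized) P equals either group's
  # covariance up to the pooled n - 1 denominator, 2(n-1)/(2n-1)
  d2 <- dplyr::bind_rows(dplyr::mutate(d, year = 1),
                         dplyr::mutate(d, year = 2))
  Pp <- p_matrix(d2, pool_by = "year")
  ds <- standardize_traits(d, scheme = "mean")
  S1 <- stats::cov(as.matrix(ds[, c("PN", "MD", "ML")]))
  n1 <- nrow(d)
  expect_equal(Pp$matrix, S1 * 2 * (n1 - 1) / (2 * n1 - 1),
               tolerance = 1e-10)
  expect_error(p_matrix(dplyr::mutate(d[1:2, ], year = 1), pool_by = "year"),
               "at least 3")
})

test_that("off-diagonals of P vanish for independent columns at large n", {
  set.seed(8)
  n <- 10000
  d <- tibble::tibble(PN = rnorm(n), MD = rnorm(n), ML = rnorm(n))
  P <- p_matrix(d)$matrix
  se <- 1 / sqrt(n) # sd of a sample covariance of unit-variance independents
  off <- P[upper.tri(P)]
  expect_true(all(abs(off) < 3 * se))
})

test_that("jackknife SEs behave as the delete-one formula requires", {
  set.seed(12)
  Z <- cbind(a = rnorm(40), b = rep(2, 40))
  se <- jackknife_se_cov(Z)
  expect_equal(se["b", "b"], 0, tolerance = 1e-12) # constant column
  # invariant to row order
  expect_equal(jackknife_se_cov(Z[sample(40), ]), se, tolerance = 1e-12)
  expect_error(jackknife_se_cov(Z[1:2, ]), "at least 3")
  # univariate variance SE vs asymptotic normal-theory formula at n = 2000
  x <- matrix(rnorm(2000, sd = 1.7), ncol = 1)
  se1 <- jackknife_se_cov(x)[1, 1]
  analytic <- sqrt(2 / (nrow(x) - 1)) * stats::var(x[, 1])
  expect_lt(abs(se1 - analytic) / analytic, 0.15)
})

test_that("d_matrix reproduces the published divergence variances from the taxon table", {
  D <- d_matrix(phymata_taxa(), reference = phymata_reference_means())
  expect_equal(D$n, 37)
  expect_within(unname(diag(D$matrix) * 10), c(0.335, 0.100, 0.236), 2e-3)
  # the reference can equally be named by taxon
  D2 <- d_matrix(phymata_taxa(), reference = "P. americana americana")
  expect_equal(D2$matrix, D$matrix, tolerance = 1e-12)
})

test_that("d_matrix matches a brute-force covariance loop and is order invariant", {
  taxa <- tibble::tibble(
    taxon = c("a", "b", "c"), n = c(5, 6, 7),
    PN_mean = c(2, 3, 4), PN_sd = 0.1,
    MD_mean = c(150, 200, 250), MD_sd = 1,
    ML_mean = c(100, 150, 120), ML_sd = 1)
  ref <- c(PN = 2, MD = 200, ML = 100)
  D <- d_matrix(taxa, reference = ref, min_n = 1)
  Ms <- sweep(cbind(taxa$PN_mean, taxa$MD_mean, taxa$ML_mean), 2, ref, "/")
  expect_equal(unname(D$matrix), loop_cov(Ms), tolerance = 1e-12)
  # taxon order does not matter
  D_rev <- d_matrix(taxa[3:1, ], reference = ref, min_n = 1)
  expect_equal(D_rev$matrix, D$matrix, tolerance = 1e-12)
  # identical taxa give the zero matrix
  taxa0 <- taxa
  taxa0$PN_mean <- 2; taxa0$MD_mean <- 200; taxa0$ML_mean <- 100
  expect_equal(unname(d_matrix(taxa0, reference = ref, min_n = 1)$matrix),
               matrix(0, 3, 3))
  taxa$PN_mean[2] <- NA
  expect_error(d_matrix(taxa, reference = ref, min_n = 1), "b")
})

test_that("the minimum-specimen filter drops small taxa with a message", {
  taxa <- phymata_taxa()
  taxa$n[1] <- 3
  expect_message(D <- d_matrix(taxa, reference = phymata_reference_means()),
                 "n < 4")
  expect_equal(D$n, 36)
})

test_that("moment estimator of D recovers planted between-taxon covariance", {
  set.seed(99)
  K <- 200; nk <- 8
  D_true <- diag(c(0.4, 0.2, 0.1))
  W <- diag(c(0.5, 0.5, 0.5))
  mus <- MASS::mvrnorm(K, mu = c(0, 0, 0), Sigma = D_true)
  rows <- do.call(rbind, lapply(seq_len(K), function(k)
    cbind(k, MASS::mvrnorm(nk, mus[k, ], W))))
  d <- tibble::tibble(taxon = rows[, 1], PN = rows[, 2], MD = rows[, 3],
                      ML = rows[, 4])
  Dh <- d_matrix_moments(d)
  # 3 x Monte-Carlo SE of a between-group variance component at K groups
  se <- sqrt(2 / K) * (diag(D_true) + diag(W) / nk)
  expect_true(all(abs(diag(Dh$matrix) - diag(D_true)) < 3 * se))

  # zero within-taxon variance: D-hat equals the covariance of taxon means
  d0 <- tibble::tibble(taxon = rep(1:5, each = 2),
                       PN = rep(rnorm(5), each = 2),
                       MD = rep(rnorm(5), each = 2),
                       ML = rep(rnorm(5), each = 2))
  Dh0 <- d_matrix_moments(d0)
  means <- as.matrix(dplyr::summarise(
    dplyr::group_by(d0, taxon),
    dplyr::across(c("PN", "MD", "ML"), mean))[, -1])
  expect_equal(unname(Dh0$matrix), unname(stats::cov(means)),
               tolerance = 1e-10)

  # shared mean with large within variance: truncated at zero with a warning
  set.seed(5)
  d1 <- tibble::tibble(taxon = rep(1:4, each = 3),
                       PN = rnorm(12, sd = 5), MD = rnorm(12, sd = 5),
                       ML = rnorm(12, sd = 5))
  expect_warning(Dh1 <- d_matrix_moments(d1), "truncated")
  ev <- eigen(Dh1$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
})
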