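test_that("relative fitness divides by the mean and guards degenerate input", {
  expect_equal(relative_fitness(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(relative_fitness(c(0, 2)), c(0, 2))
  expect_equal(relative_fitness(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(mean(relative_fitness(rpois(50, 2) + 1)), 1)
  expect_error(relative_fitness(c(0, 0, 0)), "positive fitness")
  expect_error(relative_fitness(c(-1, 2)), "non-negative")
})

test_that("beta is zero for constant fitness and exact for noiseless linear truth", {
  d <- toy_sample(80)
  d$fitness <- 2
  g <- suppressWarnings(selection_gradients(d))
  expect_equal(unname(g$beta), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(g$gamma), matrix(0, 3, 3), tolerance = 1e-12)

  zs <- scale(as.matrix(d[, c("PN", "MD", "ML")]))
  d$fitness <- 1 + 0.3 * zs[, 1]
  g2 <- suppressWarnings(selection_gradients(d))
  expect_equal(unname(g2$beta), c(0.3, 0, 0), tolerance = 1e-10)
})

test_that("beta recovers planted gradients in a large simulated sample", {
  set.seed(7)
  n <- 10000
  Z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("PN", "MD", "ML")))
  beta_true <- c(0.05, -0.1, 0.025)
  w <- 1 + Z %*% beta_true + rnorm(n, sd = 0.1) # stays positive
  expect_true(all(w > 0))
  d <- tibble::as_tibble(as.data.frame(Z))
  d$fitness <- as.vector(w)
  g <- selection_gradients(d)
  expect_true(all(abs(g$beta - beta_true) < 3 * g$beta_se))
})

test_that("gamma recovers an exact quadratic surface to machine precision", {
  # surface mild enough that expected fitness stays positive everywhere
  G <- matrix(c(0.04, 0.01, -0.02, 0.01, -0.05, 0.015, -0.02, 0.015, -0.03),
              3, 3, dimnames = list(c("PN", "MD", "ML"), c("PN", "MD", "ML")))
  b <- c(PN = 0.02, MD = -0.01, ML = 0.01)
  d <- simulate_selection_sample(
    sim_config(n_individuals = 200, fitness_model = "quadratic_exact",
               beta_true = b, gamma_true = G, fitness_noise = "none"),
    seed = 11)
  # plug the planted surface back in as the oracle for expected fitness
  zs <- scale(as.matrix(d[, c("PN", "MD", "ML")]))
  w_oracle <- 1 + zs %*% b + 0.5 * rowSums((zs %*% G) * zs)
  expect_true(all(w_oracle > 0))
  expect_equal(d$fitness, as.vector(w_oracle), tolerance = 1e-12)

  g <- suppressWarnings(selection_gradients(d, fitness = "fitness"))
  # relative fitness rescales by mean(w); undo for the comparison
  fac <- mean(w_oracle)
  expect_equal(g$gamma * fac, G, tolerance = 1e-8)
  expect_true(isSymmetric(g$gamma, tol = 1e-12))
})

test_that("quadratic doubling doubles only the diagonal", {
  d <- toy_sample(100, seed = 3)
  d$fitness <- rpois(100, 1) + 1
  g1 <- selection_gradients(d, double_quadratic = TRUE)
  g2 <- selection_gradients(d, double_quadratic = FALSE)
  expect_equal(diag(g1$gamma), 2 * diag(g2$gamma), tolerance = 1e-12)
  off <- upper.tri(g1$gamma)
  expect_equal(g1$gamma[off], g2$gamma[off], tolerance = 1e-12)
})

test_that("fit statistics use the Lande-Arnold degrees of freedom", {
  d <- toy_sample(44, seed = 5)
  d$fitness <- d$fitness + 1
  gl <- glance(selection_gradients(d))
  expect_equal(gl$df1, c(3, 9))
  expect_equal(gl$df2, c(40, 34))
  expect_equal(gl$model, c("linear", "nonlinear"))
  td <- tidy(selection_gradients(d))
  expect_equal(nrow(td), 3 + 6)
  expect_true(all(td$std.error >= 0))
})

test_that("small samples are rejected with the minimum stated", {
  d <- toy_sample(9)
  d$fitness <- d$fitness + 1
  expect_error(selection_gradients(d), "10")
})

test_that("mean standardization of gradients follows the CV rule and round-trips", {
  d <- toy_sample(80, seed = 9)
  d$fitness <- d$fitness + 1
  g <- selection_gradients(d)
  means <- c(PN = 2, MD = 4, ML = 8)
  sds <- c(PN = 0.5, MD = 1, ML = 2)
  gm <- mean_standardize_gradients(g, means, sds)
  cv <- sds / means
  expect_equal(gm$beta, g$beta / cv, tolerance = 1e-12)
  expect_equal(gm$gamma["PN", "MD"], g$gamma["PN", "MD"] / (cv[["PN"]] * cv[["MD"]]),
               tolerance = 1e-12)
  # one-trait hand check: beta_sigma = 0.2, mean 2, sd 0.5 -> beta_mu = 0.8
  expect_equal(0.2 / (0.5 / 2), 0.8)
  # all CV = 1 leaves gradients unchanged
  g_id <- mean_standardize_gradients(g, c(PN = 1, MD = 1, ML = 1),
                                     c(PN = 1, MD = 1, ML = 1))
  expect_equal(g_id$gamma, g$gamma)
  # round trip: standardize with the reciprocal CVs restores the original
  back <- mean_standardize_gradients(gm, means = sds, sds = means)
  expect_equal(back$beta, g$beta, tolerance = 1e-12)
  expect_equal(back$gamma, g$gamma, tolerance = 1e-12)
  expect_error(mean_standardize_gradients(g, c(PN = 0, MD = 1, ML = 1), sds),
               "positive")
})
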