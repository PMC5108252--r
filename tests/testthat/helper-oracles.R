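# Independent brute-force oracles, deliberately naive so they share no code
# path with the package implementation.

# double-loop sample covariance (n - 1 denominator)
loop_cov <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  mu <- numeric(p)
  for (j in 1:p) for (i in 1:n) mu[j] <- mu[j] + X[i, j] / n
  S <- matrix(0, p, p)
  for (j in 1:p) for (l in 1:p) {
    acc <- 0
    for (i in 1:n) acc <- acc + (X[i, j] - mu[j]) * (X[i, l] - mu[l])
    S[j, l] <- acc / (n - 1)
  }
  S
}

# eigenvalues of a symmetric 3x3 via the characteristic polynomial, and the
# eigenvector of each root via cross products of rows of (A - lambda I)
poly_eigen3 <- function(A) {
  stopifnot(nrow(A) == 3)
  c0 <- -det(A)
  c1 <- (A[1, 1] * A[2, 2] - A[1, 2]^2) +
    (A[1, 1] * A[3, 3] - A[1, 3]^2) +
    (A[2, 2] * A[3, 3] - A[2, 3]^2)
  c2 <- -(A[1, 1] + A[2, 2] + A[3, 3])
  lam <- sort(Re(polyroot(c(c0, c1, c2, 1))), decreasing = TRUE)
  vecs <- sapply(lam, function(l) {
    M <- A - diag(l, 3)
    v <- pracma_cross(M[1, ], M[2, ])
    if (sqrt(sum(v^2)) < 1e-10) v <- pracma_cross(M[1, ], M[3, ])
    if (sqrt(sum(v^2)) < 1e-10) v <- pracma_cross(M[2, ], M[3, ])
    v / sqrt(sum(v^2))
  })
  list(values = lam, vectors = vecs)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# explicit double-loop quadratic form m' A m
quad_form_loop <- function(m, A) {
  acc <- 0
  for (i in seq_along(m)) for (j in seq_along(m)) {
    acc <- acc + m[i] * A[i, j] * m[j]
  }
  acc
}

random_rotation <- function(p) {
  Q <- qr.Q(qr(matrix(rnorm(p * p), p)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# quick three-trait individual table with fitness, for interface tests
toy_sample <- function(n = 60, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    PN = rnorm(n, 3, 0.2), MD = rnorm(n, 236, 20), ML = rnorm(n, 213, 35),
    fitness = rpois(n, 1)
  )
}

# absolute-tolerance comparison (printed-value checks use absolute deltas)
expect_within <- function(object, expected, tol) {
  testthat::expect_lte(max(abs(object - expected)), tol)
}
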