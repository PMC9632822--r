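# Independent oracles used to cross-check the package's estimators.

# Pure-R single-trajectory RK4 for the gLV growth law; written independently
# of the compiled batch integrator (same protocol: clamp to [0, cap] after
# each full step).
rk4_reference <- function(A, theta, n0, total_time, step, cap = 1e12) {
  A <- unclass(as.matrix(A))
  f <- function(x) x * (theta - drop(A %*% x))
  N <- n0
  for (s in seq_len(round(total_time / step))) {
    k1 <- f(N)
    k2 <- f(N + step / 2 * k1)
    k3 <- f(N + step / 2 * k2)
    k4 <- f(N + step * k3)
    N <- N + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    N <- pmin(pmax(N, 0), cap)
  }
  N
}

# closed-form logistic solution N(t) for dN/dt = N (theta - a N)
logistic_closed_form <- function(theta, a, n0, t) {
  K <- theta / a
  K * n0 * exp(theta * t) / (K + n0 * (exp(theta * t) - 1))
}

# membership of a 2-D point in the conical hull of a generator set: true iff
# some pair of generators spans it with nonnegative coefficients (or it lies
# on a single generator ray)
in_conical_hull_2d <- function(z, G, tol = 1e-10) {
  m <- ncol(G)
  for (i in seq_len(m)) {
    gi <- G[, i]
    if (sum(gi^2) < tol) next
    # on the ray of a single generator
    if (abs(gi[1] * z[2] - gi[2] * z[1]) < tol && sum(gi * z) > 0) {
      return(TRUE)
    }
    for (j in seq_len(m)) {
      if (j == i) next
      M <- cbind(gi, G[, j])
      dt <- det(M)
      if (abs(dt) < tol) next
      lam <- solve(M, z)
      if (all(lam >= -tol)) return(TRUE)
    }
  }
  FALSE
}

# brute-force rejection estimate of the sphere-box acceptance fraction
box_acceptance_oracle <- function(dim, lo, hi, n, seed) {
  withr::with_seed(seed, {
    g <- matrix(stats::rnorm(n * dim), n, dim)
    g <- g / sqrt(rowSums(g^2))
    mean(rowSums(g >= lo & g <= hi) == dim)
  })
}

# shorthand: 4-sigma binomial tolerance for a proportion estimated from n
binom4se <- function(p, n) 4 * sqrt(p * (1 - p) / n)

expect_within <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %.3g", actual, expected, tol))
}
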