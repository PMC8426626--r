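# Shared fixtures, all generated in code.

# Small multivariate-normal table with scattered missingness.
random_incomplete <- function(n, p, miss_rate = 0.2, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  sigma <- crossprod(A) / p + diag(0.5, p)
  L <- chol(sigma)
  x <- matrix(rnorm(n * p), n) %*% L
  x <- sweep(x, 2, rnorm(p), "+")
  miss <- matrix(runif(n * p) < miss_rate, n, p)
  # keep every row partially observed
  full_miss <- rowSums(!miss) == 0
  miss[full_miss, 1] <- FALSE
  x[miss] <- NA
  colnames(x) <- paste0("V", seq_len(p))
  as.data.frame(x)
}

# Population two-factor parameter vector (loadings, phi, error vars, means).
two_factor_theta <- function(lambda = 0.49, phi = 0.4) {
  c(rep(lambda, 8), phi, rep(1 - lambda^2, 8), rep(0, 8))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-10)), tol)
}
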