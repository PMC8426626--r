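test_that("pattern partition groups rows by missingness mask", {
  # complete data: a single pattern with the ML covariance
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 1, 4, 3))
  ps <- pattern_partition(d)
  expect_length(ps$patterns, 1L)
  expect_equal(ps$patterns[[1]]$S, cov(d) * 3 / 4, ignore_attr = TRUE)

  # hand-enumerated masks
  d2 <- data.frame(a = c(1, NA, 3), b = c(NA, 2, 4))
  ps2 <- pattern_partition(d2)
  expect_length(ps2$patterns, 3L)
  expect_equal(sort(vapply(ps2$patterns, function(p) p$n, numeric(1))),
               c(1, 1, 1))

  # all-missing rows are dropped with a warning and counted
  d3 <- data.frame(a = c(1, NA, 2), b = c(1, NA, NA))
  expect_warning(ps3 <- pattern_partition(d3), "all-missing")
  expect_equal(ps3$n_dropped_empty, 1L)
  expect_equal(ps3$N, 2L)
  suppressWarnings(
    expect_error(pattern_partition(data.frame(a = NA_real_)),
                 class = "fmitools_empty_data"))
})

test_that("missingness confined to X yields exactly two patterns", {
  mech <- regression_mechanism("mcar", 0.2)
  dat <- simulate_dataset("regression", 1000, mech, seed = 42)
  ps <- pattern_partition(dat)
  expect_length(ps$patterns, 2L)
  expect_equal(sum(vapply(ps$patterns, function(p) p$n, numeric(1))), 1000)
})

test_that("observed log-likelihood matches closed forms and a row-wise oracle", {
  sat2 <- saturated_model(2)
  # one complete case at the mean of a standard bivariate normal
  ps <- pattern_partition(data.frame(a = 0, b = 0))
  expect_equal(observed_loglik(sat2, c(0, 0, 1, 0, 1), ps), -log(2 * pi))

  # one case observing only the second variable
  ps2 <- pattern_partition(data.frame(a = NA_real_, b = 0))
  expect_equal(observed_loglik(sat2, c(0, 0, 1, 0, 1), ps2), -0.5 * log(2 * pi))

  # pattern-wise evaluation equals a naive case-by-case sum
  d <- random_incomplete(50, 3, 0.25, seed = 7)
  sat3 <- saturated_model(3)
  mu <- c(0.2, -0.1, 0.4)
  sigma <- matrix(c(1.5, 0.3, 0.2, 0.3, 1.2, 0.4, 0.2, 0.4, 2.0), 3)
  theta <- c(mu, sigma[lower.tri(sigma, diag = TRUE)])
  rowwise <- sum(vapply(seq_len(nrow(d)), function(i) {
    obs <- which(!is.na(d[i, ]))
    x <- as.numeric(d[i, obs])
    k <- length(obs)
    s <- sigma[obs, obs, drop = FALSE]
    -k / 2 * log(2 * pi) - 0.5 * determinant(s)$modulus[1] -
      0.5 * t(x - mu[obs]) %*% solve(s) %*% (x - mu[obs])
  }, numeric(1)))
  expect_equal(observed_loglik(sat3, theta, pattern_partition(d)), rowwise,
               tolerance = 1e-10)
})

test_that("complete-data FIML equals closed-form ML", {
  d <- simulate_regression_population(300, seed = 11)
  fit <- fit_fiml(d, regression_model())
  expect_true(fit$converged)
  ols <- lm(Y ~ X, data = d)
  expect_equal(unname(fit$theta["beta"]), unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(unname(fit$theta["alpha"]), unname(coef(ols)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$theta["psi"]),
               sum(residuals(ols)^2) / nrow(d), tolerance = 1e-6)
  expect_equal(unname(fit$theta["mu_x"]), mean(d$X), tolerance = 1e-7)
  expect_equal(unname(fit$theta["phi_x"]), var(d$X) * 299 / 300,
               tolerance = 1e-6)

  # saturated model recovers the sample moments
  sfit <- fit_fiml(d, saturated_model(2, c("X", "Y")))
  expect_equal(unname(sfit$theta[1:2]), c(mean(d$X), mean(d$Y)),
               tolerance = 1e-6)
  S <- cov(d) * 299 / 300
  expect_equal(unname(sfit$theta[3:5]), c(S[1, 1], S[2, 1], S[2, 2]),
               tolerance = 1e-5)
})

test_that("FIML estimates are invariant to row permutation", {
  mech <- regression_mechanism("mar_linear", 0.4)
  dat <- simulate_dataset("regression", 400, mech, seed = 13)
  f1 <- fit_fiml(dat, regression_model())
  set.seed(99)
  f2 <- fit_fiml(dat[sample(nrow(dat)), ], regression_model())
  expect_equal(f1$theta, f2$theta, tolerance = 1e-10)
})

test_that("saturated EM fit dominates the structured fit in likelihood", {
  mech <- two_factor_mechanism("mcar", 0.4)
  dat <- simulate_dataset("two_factor", 300, mech, seed = 17)
  pats <- pattern_partition(dat)
  cfa <- fit_fiml(pats, two_factor_model())
  em <- fit_saturated_em(pats)
  expect_true(cfa$converged)
  expect_gte(em$loglik, cfa$loglik)
})

test_that("wrong-length start vector is a configuration error", {
  d <- simulate_regression_population(50, seed = 1)
  expect_error(fit_fiml(d, regression_model(), start = c(0, 1)),
               class = "fmitools_config_error")
})

test_that("EM: one-step on complete data, monotone trace, optimizer agreement", {
  d <- simulate_regression_population(150, seed = 21)
  em <- fit_saturated_em(d)
  expect_true(em$converged)
  expect_equal(unname(em$moments$mu), c(mean(d$X), mean(d$Y)),
               tolerance = 1e-12)
  expect_equal(unname(em$moments$sigma), unname(as.matrix(cov(d) * 149 / 150)),
               tolerance = 1e-12)

  # incomplete bivariate: EM agrees with direct maximization, trace ascends
  d$X[seq(1, 150, by = 3)] <- NA
  em2 <- fit_saturated_em(d)
  expect_true(all(diff(em2$loglik_trace) >= -1e-8))
  direct <- fit_fiml(d, saturated_model(2, c("X", "Y")))
  expect_equal(c(em2$moments$mu, em2$moments$sigma[lower.tri(em2$moments$sigma, diag = TRUE)]),
               unname(direct$theta), tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("two-factor FIML recovers population loadings at large N", {
  dat <- simulate_two_factor_population(50000, seed = 31)
  fit <- fit_fiml(dat, two_factor_model())
  expect_true(fit$converged)
  # MC standard error of a loading at N = 5e4 is about 0.005
  expect_equal(unname(fit$theta["lambda_X2"]), 0.49, tolerance = 0.015)
  expect_equal(unname(fit$theta["phi_F1.F2"]), 0.4, tolerance = 0.02)
})

test_that("tidy and glance return well-formed tibbles", {
  d <- simulate_regression_population(100, seed = 3)
  fit <- fit_fiml(d, regression_model())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "role", "estimate"))
  expect_equal(nrow(td), 5L)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 100L)
})
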