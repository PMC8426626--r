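test_that("numeric Hessian is exact on quadratics and stable under step halving", {
  A <- matrix(c(2, 1, 1, 3), 2)
  f <- function(x) 0.5 * drop(t(x) %*% A %*% x)
  expect_equal(numeric_hessian(f, c(0.3, -0.2)), A, tolerance = 1e-6)

  # smooth non-quadratic: halving the step changes the result negligibly
  g <- function(x) sum(sin(x)) + exp(0.3 * x[1]) * x[2]
  H1 <- numeric_hessian(g, c(0.4, 0.7))
  H2 <- numeric_hessian(g, c(0.4, 0.7), h_scale = 5e-5)
  expect_lt(max(abs(H1 - H2)) / max(abs(H2)), 1e-5)

  suppressWarnings(
    expect_error(numeric_hessian(function(x) sqrt(x[1]), 1e-9),
                 class = "fmitools_differentiation_error"))
})

test_that("observed information matches univariate and OLS closed forms", {
  # univariate normal: info diag = (N / sigma^2, N / (2 sigma^4)) at the MLE
  set.seed(5)
  x <- data.frame(v = rnorm(80))
  fit <- fit_fiml(x, saturated_model(1, "v"))
  s2 <- unname(fit$theta[2])
  info <- observed_info_hessian(fit)
  expect_rel_equal(diag(unclass(info)), c(80 / s2, 80 / (2 * s2^2)), 1e-4)

  # complete-data regression: SEs from inverse info equal OLS ML SEs
  d <- simulate_regression_population(250, seed = 23)
  rfit <- fit_fiml(d, regression_model())
  info_r <- observed_info_hessian(rfit)
  se <- sqrt(diag(solve(unclass(info_r))))
  names(se) <- rownames(info_r)
  psi <- unname(rfit$theta["psi"])
  sxx <- sum((d$X - mean(d$X))^2)
  expect_equal(unname(se["beta"]), sqrt(psi / sxx), tolerance = 1e-3)
  expect_equal(unname(se["mu_x"]),
               sqrt(unname(rfit$theta["phi_x"]) / 250), tolerance = 1e-3)
})

test_that("analytic unstructured information equals the numeric Hessian (normative)", {
  # randomized incomplete datasets of varying dimension, arbitrary admissible
  # moments: the closed-form pattern accumulation must reproduce the curvature
  for (seed in 1:6) {
    p <- 2 + seed %% 3
    d <- random_incomplete(40 + 10 * seed, p, 0.25, seed = seed)
    pats <- pattern_partition(d)
    set.seed(seed + 100)
    B <- matrix(rnorm(p * p), p)
    sigma <- crossprod(B) / p + diag(0.7, p)
    mu <- rnorm(p, sd = 0.5)
    H1 <- h1_observed_info(list(mu = mu, sigma = sigma), pats)
    sat <- saturated_model(p)
    Hn <- -numeric_hessian(function(th) observed_loglik(sat, th, pats),
                           c(mu, sigma[lower.tri(sigma, diag = TRUE)]))
    expect_lt(max(abs(H1 - Hn)) / max(abs(Hn)), 1e-5)
  }
})

test_that("complete-data h1 information has zero cross block and N Sigma^-1 mean block", {
  d <- simulate_regression_population(120, seed = 41)
  pats <- pattern_partition(d)
  mu <- colMeans(d)
  S <- cov(d) * 119 / 120
  H1 <- h1_observed_info(list(mu = mu, sigma = S), pats)
  expect_equal(H1[1:2, 3:5], matrix(0, 2, 3), tolerance = 1e-8)
  expect_equal(H1[1:2, 1:2], 120 * solve(S), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("information scales linearly in N for fixed moments", {
  d <- random_incomplete(60, 3, 0.3, seed = 9)
  pats <- pattern_partition(d)
  M <- list(mu = c(0, 0, 0), sigma = diag(3) + 0.2)
  H <- h1_observed_info(M, pats)
  pats2 <- pats
  pats2$patterns <- lapply(pats2$patterns, function(pt) {
    pt$n <- 2 * pt$n
    pt
  })
  pats2$N <- 2L * pats2$N
  expect_equal(h1_observed_info(M, pats2), 2 * H, tolerance = 1e-12)
})

test_that("complete-data information: pseudo-sample closed form and FMI ~ 0", {
  # saturated p = 1 at moments (0, 1), N = 100 -> diag(100, 50)
  fit1 <- list(model = saturated_model(1), theta = c(mu_V1 = 0, cov_V1.V1 = 1),
               N = 100L,
               patterns = pattern_partition(data.frame(V1 = rnorm(5))))
  class(fit1) <- "fiml_fit"
  ci <- complete_info(fit1, "analytic_structured", N = 100)
  expect_equal(diag(unclass(ci)), c(mu_V1 = 100, cov_V1.V1 = 50),
               tolerance = 1e-8)
  ch <- complete_info(fit1, "hessian", N = 100)
  expect_rel_equal(diag(unclass(ch)), c(100, 50), 1e-4)

  # with no missing data observed and complete information coincide
  d <- simulate_regression_population(200, seed = 43)
  fit <- fit_fiml(d, regression_model())
  oi <- observed_info_hessian(fit)
  ci2 <- complete_info(fit, "hessian")
  expect_rel_equal(diag(unclass(ci2)), diag(unclass(oi)), 1e-3)
})

test_that("observed information dominates complete at the population scale", {
  mech <- regression_mechanism("mcar", 0.4)
  dat <- simulate_dataset("regression", 20000, mech, seed = 51)
  fit <- fit_fiml(dat, regression_model())
  JY <- observed_info_hessian(fit)
  JX <- complete_info(fit, "hessian")
  expect_true(all(diag(solve(unclass(JY))) >= diag(solve(unclass(JX)))))
})

test_that("analytic variants: saturated model identity and CSV export", {
  d <- random_incomplete(80, 2, 0.3, seed = 55)
  fit <- fit_fiml(d, saturated_model(2))
  ia <- observed_info_analytic(fit, "implied")
  ih <- h1_observed_info(implied_moments(fit$model, fit$theta), fit$patterns)
  expect_equal(unclass(ia), ih, tolerance = 1e-10, ignore_attr = TRUE)

  tmp <- tempfile(fileext = ".csv")
  write_info_csv(ia, tmp)
  back <- readr::read_csv(tmp, show_col_types = FALSE)
  expect_equal(nrow(back), 5L)
  expect_equal(back$parameter, rownames(ia))
})
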