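test_that("population generators reproduce the stated moments", {
  n <- 200000
  d <- simulate_regression_population(n, seed = 81)
  expect_lt(abs(cor(d$X, d$Y) - 0.4), 0.008)
  expect_lt(abs(sd(d$Y) - 1), 0.008)
  expect_lt(abs(sd(d$X) - 1), 0.008)

  # same seed reproduces the table bit for bit
  expect_identical(d, simulate_regression_population(n, seed = 81))

  tf <- simulate_two_factor_population(n, seed = 82)
  expect_lt(abs(cov(tf$X1, tf$X3) - 0.49^2), 0.008)
  expect_lt(abs(cov(tf$X1, tf$Y1) - 0.49 * 0.4 * 0.49), 0.008)
  expect_lt(abs(var(tf$X2) - 1), 0.01)
  expect_identical(tf, simulate_two_factor_population(n, seed = 82))
})

test_that("MAR cutoffs match the closed-form percentile construction", {
  # pi_c = (0.2 - 0.9) / (0.1 - 0.9) = 0.875; qnorm(0.875) = 1.1503
  c1 <- mar_cutoffs(0.2, type = "mar_linear")
  expect_equal(c1$pi_c, 0.875)
  expect_equal(c1$cutoffs, qnorm(0.875), tolerance = 1e-10)
  expect_equal(round(c1$cutoffs, 2), 1.15)

  c2 <- mar_cutoffs(0.2, type = "mar_nonlinear")
  expect_equal(c2$cutoffs, c(-1, 1) * qnorm(0.5 + 0.5 * 0.875))
  expect_equal(round(c2$cutoffs[2], 2), 1.53)

  c3 <- mar_cutoffs(0.6, type = "mar_linear")
  expect_equal(c3$pi_c, 0.375)
  expect_equal(round(c3$cutoffs, 2), -0.32)

  c4 <- mar_cutoffs(0.4, type = "mar_linear")
  expect_equal(c4$pi_c, 0.625)
  expect_equal(round(c4$cutoffs, 2), 0.32)

  expect_error(mar_cutoffs(0.95, type = "mar_linear"),
               class = "fmitools_mechanism_error")
})

test_that("mechanism rate identity holds algebraically and empirically", {
  # pi1 (1 - pi_c) + pi2 pi_c = pi_mis by construction
  for (m in c(0.2, 0.4, 0.6)) {
    pc <- mar_cutoffs(m, type = "mar_linear")$pi_c
    expect_equal(0.9 * (1 - pc) + 0.1 * pc, m, tolerance = 1e-12)
  }
  # realized rate at large N
  mech <- regression_mechanism("mar_linear", 0.4)
  dat <- simulate_dataset("regression", 200000, mech, seed = 85)
  expect_lt(abs(unname(realized_rates(dat)["X"]) - 0.4), 0.005)

  mech_nl <- regression_mechanism("mar_nonlinear", 0.6)
  dat_nl <- simulate_dataset("regression", 200000, mech_nl, seed = 86)
  expect_lt(abs(unname(realized_rates(dat_nl)["X"]) - 0.6), 0.005)
})

test_that("MCAR realized rates stay within binomial bounds", {
  for (n in c(100, 1000, 10000)) {
    mech <- two_factor_mechanism("mcar", 0.2)
    dat <- simulate_dataset("two_factor", n, mech, seed = 87 + n)
    tol <- 4 * sqrt(0.2 * 0.8 / n)
    expect_true(all(abs(realized_rates(dat) - 0.2) <= tol))
    # overall missing-cell fraction is half the per-variable rate
    if (n == 10000)
      expect_lt(abs(mean(is.na(as.matrix(dat))) - 0.1), 0.012)
  }
})

test_that("deterministic selection limit: missing iff beyond the cutoff", {
  mech <- missing_mechanism("mar_linear", 0.5,
    groups = list(list(targets = "X",
                       conditioner = list(vars = "Y", sd = 1))),
    pi1 = 1 - 1e-12, pi2 = 1e-12)
  d <- simulate_regression_population(2000, seed = 91)
  obs <- impose_missingness(d, mech, seed = 92)
  cut <- mech$cutoffs[1]
  expect_equal(is.na(obs$X), d$Y > cut)
})

test_that("conditioners are protected and never missing", {
  mech <- two_factor_mechanism("mar_nonlinear", 0.4)
  dat <- simulate_dataset("two_factor", 2000, mech, seed = 93)
  expect_false(anyNA(dat[c("X1", "X3", "Y1", "Y3")]))
  # conditioning on a variable that itself goes missing is refused
  expect_error(
    missing_mechanism("mar_linear", 0.3,
      groups = list(list(targets = "Y",
                         conditioner = list(vars = "Y", sd = 1)))),
    class = "fmitools_mechanism_error")
})

test_that("indicator pairs share one missingness draw per row", {
  mech <- two_factor_mechanism("mcar", 0.4)
  dat <- simulate_dataset("two_factor", 5000, mech, seed = 95)
  expect_identical(is.na(dat$X2), is.na(dat$X4))
  expect_identical(is.na(dat$Y2), is.na(dat$Y4))
  expect_false(identical(is.na(dat$X2), is.na(dat$Y2)))
})

test_that("the complete table is preserved alongside the observed one", {
  mech <- regression_mechanism("mcar", 0.3)
  dat <- simulate_dataset("regression", 500, mech, seed = 97)
  complete <- attr(dat, "complete")
  obs_idx <- !is.na(dat$X)
  expect_equal(dat$X[obs_idx], complete$X[obs_idx])
  expect_identical(dat$Y, complete$Y)
  # swapping the mechanism leaves the complete data untouched
  dat2 <- simulate_dataset("regression", 500,
                           regression_mechanism("mar_linear", 0.3), seed = 97)
  expect_identical(attr(dat2, "complete"), complete)
})
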