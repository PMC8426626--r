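#' Simulate the regression population
#'
#' Draws `n` cases from the path model `Y = 0.4 X + E` with `X ~ N(0, 1)` and
#' `E ~ N(0, 1 - 0.4^2)`, so both variables are standard normal and the
#' implied correlation is the slope.
#'
#' @param n Number of cases.
#' @param seed Integer seed.
#' @param beta Slope (default 0.4).
#' @return A tibble with columns `X`, `Y`.
#' @export
simulate_regression_population <- function(n, seed, beta = 0.4) {
  stopifnot(n >= 1)
  set.seed(seed)
  X <- stats::rnorm(n)
  Y <- beta * X + stats::rnorm(n, sd = sqrt(1 - beta^2))
  tibble::tibble(X = X, Y = Y)
}

#' Simulate the two-factor population
#'
#' Draws `n` cases from the two-factor model: latent `(F1, F2)` bivariate
#' standard normal with correlation `phi`, and eight indicators
#' `X1..X4 = lambda * F1 + e`, `Y1..Y4 = lambda * F2 + e` with error
#' variance `1 - lambda^2`, so every indicator has unit variance.
#'
#' @param n Number of cases.
#' @param seed Integer seed.
#' @param lambda Common loading (default 0.49).
#' @param phi Factor correlation (default 0.4).
#' @return A tibble with columns `X1..X4`, `Y1..Y4`.
#' @export
simulate_two_factor_population <- function(n, seed, lambda = 0.49, phi = 0.4) {
  stopifnot(n >= 1)
  set.seed(seed)
  f1 <- stats::rnorm(n)
  f2 <- phi * f1 + stats::rnorm(n, sd = sqrt(1 - phi^2))
  ev <- sqrt(1 - lambda^2)
  out <- lapply(1:4, function(i) lambda * f1 + stats::rnorm(n, sd = ev))
  out <- c(out, lapply(1:4, function(i) lambda * f2 + stats::rnorm(n, sd = ev)))
  names(out) <- c(paste0("X", 1:4), paste0("Y", 1:4))
  tibble::as_tibble(out)
}

#' MAR cutoffs from target missing rates
#'
#' Solves the selection rates for the strong-MAR mechanisms: with missing
#' probability `pi1` in the high-risk region and `pi2` elsewhere, the region
#' mass `pi_c = (pi_mis - pi1) / (pi2 - pi1)` makes the marginal per-variable
#' missing rate exactly `pi_mis`. The linear mechanism uses the single cutoff
#' `qnorm(pi_c)` on the standardized conditioner; the nonlinear mechanism
#' uses the symmetric pair `±qnorm(0.5 + 0.5 pi_c)`.
#'
#' @param pi_mis Target per-variable missing rate, strictly between `pi2`
#'   and `pi1`.
#' @param pi1 Missing probability in the high-risk region (default 0.9).
#' @param pi2 Missing probability in the low-risk region (default 0.1).
#' @param type `"mar_linear"` or `"mar_nonlinear"`.
#' @return List with `pi_c` and `cutoffs` (length 1 or 2).
#' @examples
#' mar_cutoffs(0.2, type = "mar_linear")    # pi_c = 0.875, cutoff 1.15
#' mar_cutoffs(0.2, type = "mar_nonlinear") # cutoffs +/- 1.53
#' @export
mar_cutoffs <- function(pi_mis, pi1 = 0.9, pi2 = 0.1,
                        type = c("mar_linear", "mar_nonlinear")) {
  type <- match.arg(type)
  if (!(pi2 < pi_mis && pi_mis < pi1))
    abort_fmi("rates must satisfy pi2 < pi_mis < pi1",
              "fmitools_mechanism_error")
  pi_c <- (pi_mis - pi1) / (pi2 - pi1)
  cut <- if (type == "mar_linear") stats::qnorm(pi_c)
         else c(-1, 1) * stats::qnorm(0.5 + 0.5 * pi_c)
  list(pi_c = pi_c, cutoffs = cut)
}

#' Define a missingness mechanism
#'
#' Describes how missing cells are imposed on target variables. Targets are
#' organized into groups; each group draws one Bernoulli missingness
#' indicator per row, shared by all its targets, so variables in a group go
#' missing together (a group of one gives an ordinary per-variable draw).
#' Under `"mcar"` the group indicator fires at rate `pi_mis` regardless of
#' the data; under `"mar_linear"` it fires with probability `pi1` when the
#' group's standardized conditioner exceeds a single cutoff and `pi2`
#' otherwise; `"mar_nonlinear"` uses `pi1` outside a symmetric cutoff pair
#' and `pi2` between them. Conditioners are sums of fully observed
#' variables, standardized by their theoretical population SD so that the
#' cutoffs apply on the standard-normal scale.
#'
#' @param type `"mcar"`, `"mar_linear"` or `"mar_nonlinear"`.
#' @param pi_mis Target per-variable missing rate in `(0, 1)`.
#' @param groups List of groups, each a list with `targets` (character) and,
#'   for MAR types, `conditioner = list(vars = <character>, sd =
#'   <theoretical SD of the sum>)`. A plain character vector is accepted as
#'   shorthand for one-variable groups (MCAR only).
#' @param pi1,pi2 High- and low-risk missing probabilities (defaults 0.9 and
#'   0.1).
#' @return An object of class `fmi_mechanism`.
#' @export
missing_mechanism <- function(type = c("mcar", "mar_linear", "mar_nonlinear"),
                              pi_mis, groups, pi1 = 0.9, pi2 = 0.1) {
  type <- match.arg(type)
  stopifnot(pi_mis > 0, pi_mis < 1)
  if (is.character(groups))
    groups <- lapply(groups, function(v) list(targets = v))
  targets <- unlist(lapply(groups, `[[`, "targets"))
  if (length(targets) < 1L || anyDuplicated(targets) > 0L)
    abort_fmi("groups must cover at least one target, each target once",
              "fmitools_mechanism_error")
  pi_c <- NA_real_
  cutoffs <- numeric()
  if (type != "mcar") {
    mc <- mar_cutoffs(pi_mis, pi1, pi2, type)
    pi_c <- mc$pi_c
    cutoffs <- mc$cutoffs
    if (!all(vapply(groups, function(g) !is.null(g$conditioner), logical(1))))
      abort_fmi("every group needs a conditioner under MAR",
                "fmitools_mechanism_error")
    cond_vars <- unique(unlist(lapply(groups,
                                      function(g) g$conditioner$vars)))
    if (any(cond_vars %in% targets))
      abort_fmi("a conditioning variable may not also receive missingness (would be MNAR)",
                "fmitools_mechanism_error")
  }
  structure(
    list(type = type, pi_mis = pi_mis, pi1 = pi1, pi2 = pi2, pi_c = pi_c,
         cutoffs = cutoffs, targets = targets, groups = groups),
    class = "fmi_mechanism"
  )
}

#' @export
print.fmi_mechanism <- function(x, ...) {
  cat("<fmi_mechanism>", x$type, "| pi_mis =", x$pi_mis,
      "| targets:", paste(x$targets, collapse = ", "), "\n")
  if (x$type != "mcar")
    cat("  pi1 =", x$pi1, "pi2 =", x$pi2, "pi_c =", round(x$pi_c, 4),
        "cutoffs:", paste(round(x$cutoffs, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Study-design mechanisms for the two population models
#'
#' `regression_mechanism()` targets `X` with missingness conditioned on `Y`
#' (theoretical SD 1). `two_factor_mechanism()` deletes the indicator pair
#' `X2, X4` with one shared draw per row and the pair `Y2, Y4` with another;
#' under MAR the pairs are conditioned on `X1 + X3` and `Y1 + Y3`
#' respectively, each standardized by the theoretical SD
#' `sqrt(2 + 2 lambda^2)` of the sum.
#'
#' @inheritParams missing_mechanism
#' @param lambda Loading used for the conditioner SD (default 0.49).
#' @return An `fmi_mechanism`.
#' @export
regression_mechanism <- function(type, pi_mis, pi1 = 0.9, pi2 = 0.1) {
  missing_mechanism(type, pi_mis,
                    groups = list(list(targets = "X",
                                       conditioner = list(vars = "Y", sd = 1))),
                    pi1 = pi1, pi2 = pi2)
}

#' @rdname regression_mechanism
#' @export
two_factor_mechanism <- function(type, pi_mis, pi1 = 0.9, pi2 = 0.1,
                                 lambda = 0.49) {
  sd_sum <- sqrt(2 + 2 * lambda^2)
  missing_mechanism(type, pi_mis, groups = list(
    list(targets = c("X2", "X4"),
         conditioner = list(vars = c("X1", "X3"), sd = sd_sum)),
    list(targets = c("Y2", "Y4"),
         conditioner = list(vars = c("Y1", "Y3"), sd = sd_sum))),
    pi1 = pi1, pi2 = pi2)
}

#' Impose missingness on complete data
#'
#' Applies a mechanism to a complete data table. Each target group draws one
#' Bernoulli indicator per row, shared by the group's variables; groups draw
#' independently of one another. Conditioning variables are never deleted.
#'
#' @param data Complete numeric data frame.
#' @param mechanism An [`fmi_mechanism`].
#' @param seed Integer seed for the missingness draw.
#' @return The observed data as a tibble of class `fmi_simdata`, with the
#'   complete table, the mechanism, the seed and the per-target realized
#'   missing rates attached as attributes `"complete"`, `"mechanism"`,
#'   `"seed"`, `"realized_rates"`.
#' @export
impose_missingness <- function(data, mechanism, seed) {
  stopifnot(inherits(mechanism, "fmi_mechanism"))
  complete <- tibble::as_tibble(data)
  if (!all(mechanism$targets %in% names(complete)))
    abort_fmi("target variables absent from the data", "fmitools_mechanism_error")
  if (mechanism$type != "mcar") {
    cond_vars <- unique(unlist(lapply(mechanism$groups,
                                      function(g) g$conditioner$vars)))
    if (anyNA(complete[cond_vars]))
      abort_fmi("conditioning variables must be fully observed",
                "fmitools_mechanism_error")
  }
  set.seed(seed)
  out <- complete
  n <- nrow(complete)
  rates <- stats::setNames(numeric(length(mechanism$targets)),
                           mechanism$targets)
  for (g in mechanism$groups) {
    pmiss <- if (mechanism$type == "mcar") {
      rep(mechanism$pi_mis, n)
    } else {
      cd <- g$conditioner
      z <- rowSums(complete[, cd$vars, drop = FALSE]) / cd$sd
      high <- if (mechanism$type == "mar_linear") {
        z > mechanism$cutoffs[1L]
      } else {
        z < mechanism$cutoffs[1L] | z > mechanism$cutoffs[2L]
      }
      ifelse(high, mechanism$pi1, mechanism$pi2)
    }
    miss <- stats::runif(n) < pmiss
    for (tg in g$targets) {
      out[[tg]][miss] <- NA
      rates[tg] <- mean(miss)
    }
  }
  structure(out, complete = complete, mechanism = mechanism, seed = seed,
            realized_rates = rates,
            class = c("fmi_simdata", class(out)))
}

#' Simulate a complete-plus-observed dataset
#'
#' One master seed per dataset: the complete-data draw and the missingness
#' draw consume disjoint substreams, so mechanisms can be swapped on
#' identical complete data.
#'
#' @param population `"regression"` or `"two_factor"`.
#' @param n Sample size.
#' @param mechanism An [`fmi_mechanism`].
#' @param seed Master seed.
#' @return An `fmi_simdata` tibble (see [impose_missingness()]).
#' @export
simulate_dataset <- function(population = c("regression", "two_factor"),
                             n, mechanism, seed) {
  population <- match.arg(population)
  complete <- switch(population,
    regression = simulate_regression_population(n, substream_seed(seed, 0L)),
    two_factor = simulate_two_factor_population(n, substream_seed(seed, 0L)))
  impose_missingness(complete, mechanism, substream_seed(seed, 1L))
}

#' Realized missing rates of a simulated dataset
#'
#' @param x An `fmi_simdata` object.
#' @return Named numeric vector of per-target missing fractions.
#' @export
realized_rates <- function(x) attr(x, "realized_rates")
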