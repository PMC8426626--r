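# Monte-Carlo evaluation harness: pseudo-population FMIs at very large N,
# replication loops over condition cells, and bias/RMSE/ETI summaries with
# failure accounting.

pop_model_for <- function(population) {
  switch(population,
         regression = regression_model(),
         two_factor = two_factor_model(),
         abort_fmi("unknown population", "fmitools_config_error"))
}

mechanism_for <- function(population, type, pi_mis) {
  switch(population,
         regression = regression_mechanism(type, pi_mis),
         two_factor = two_factor_mechanism(type, pi_mis))
}

#' Define a simulation condition
#'
#' One cell of the Monte-Carlo design: population model, missingness
#' mechanism, per-variable missing rate, sample size, replication count and
#' base seed. Replicate `i` uses master seed `base_seed + i`.
#'
#' @param population `"regression"` or `"two_factor"`.
#' @param mechanism `"mcar"`, `"mar_linear"` or `"mar_nonlinear"`.
#' @param pi_mis Per-variable missing rate (the study grid uses 0.2, 0.4,
#'   0.6).
#' @param n Sample size.
#' @param n_rep Number of replications (default 1000).
#' @param base_seed Integer base seed.
#' @param methods FMI variants to compute.
#' @return A list of class `fmi_condition`.
#' @export
simulation_condition <- function(population = c("regression", "two_factor"),
                                 mechanism = c("mcar", "mar_linear",
                                               "mar_nonlinear"),
                                 pi_mis, n, n_rep = 1000L, base_seed = 1L,
                                 methods = c("delta1", "delta2", "delta3")) {
  population <- match.arg(population)
  mechanism <- match.arg(mechanism)
  structure(list(population = population, mechanism = mechanism,
                 pi_mis = pi_mis, n = as.integer(n), n_rep = as.integer(n_rep),
                 base_seed = as.integer(base_seed), methods = methods),
            class = "fmi_condition")
}

#' Pseudo-population FMI from one very large sample
#'
#' Computes the FMI of every model parameter from a single simulated dataset
#' of size `n_pop` (one million by default), standing in for the asymptotic
#' value. All three variants are computed; they must agree — the maximum
#' cross-method discrepancy is attached as attribute
#' `"max_method_discrepancy"` — and the unstructured (`delta3`) values are
#' reported as `delta_pop`. A non-converged population fit is a hard error.
#'
#' @param population `"regression"` or `"two_factor"`.
#' @param mechanism Mechanism type string or an [`fmi_mechanism`].
#' @param pi_mis Per-variable missing rate (ignored when a full mechanism
#'   object is supplied).
#' @param n_pop Pseudo-population size (default `1e6`).
#' @param seed Master seed.
#' @return A tibble `parameter`, `delta_pop` with the discrepancy attribute.
#' @export
pseudo_population_fmi <- function(population, mechanism, pi_mis = NULL,
                                  n_pop = 1e6, seed = 1L) {
  mech <- if (inherits(mechanism, "fmi_mechanism")) mechanism
          else mechanism_for(population, mechanism, pi_mis)
  model <- pop_model_for(population)
  dat <- simulate_dataset(population, n_pop, mech, seed)
  tab <- compute_fmi(dat, model)
  fit <- attr(tab, "fit")
  if (!fit$converged)
    abort_fmi("population-scale FIML fit failed to converge",
              "fmitools_population_error")
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(tab)[, c("parameter", "method", "fmi")],
    names_from = "method", values_from = "fmi")
  disc <- max(abs(wide$delta1_hessian - wide$delta3_unstructured),
              abs(wide$delta2_structured - wide$delta3_unstructured),
              na.rm = TRUE)
  out <- tibble::tibble(parameter = wide$parameter,
                        delta_pop = wide$delta3_unstructured)
  attr(out, "max_method_discrepancy") <- disc
  attr(out, "fmi_table") <- tab
  out
}

#' Raw bias of FMI estimates
#'
#' Mean of the sample estimates minus the pseudo-population value.
#'
#' @param estimates Numeric vector of valid FMI estimates.
#' @param delta_pop Pseudo-population FMI.
#' @return A scalar.
#' @export
bias_fmi <- function(estimates, delta_pop) {
  if (length(estimates) == 0L)
    abort_fmi("no estimates supplied", "fmitools_empty_data")
  mean(estimates) - delta_pop
}

#' Root mean squared error of FMI estimates
#'
#' @inheritParams bias_fmi
#' @return `sqrt(mean((estimates - delta_pop)^2))`.
#' @export
rmse_fmi <- function(estimates, delta_pop) {
  if (length(estimates) == 0L)
    abort_fmi("no estimates supplied", "fmitools_empty_data")
  sqrt(mean((estimates - delta_pop)^2))
}

#' 95% equal-tailed interval width
#'
#' Difference between the 97.5th and 2.5th percentiles of the Monte-Carlo
#' estimates, using linear-interpolation quantiles (`type = 7`).
#'
#' @param estimates Numeric vector (at least 2 values).
#' @param level Interval level (default 0.95).
#' @return A scalar width.
#' @export
eti_width <- function(estimates, level = 0.95) {
  if (length(estimates) < 2L)
    abort_fmi("need at least two estimates", "fmitools_empty_data")
  a <- (1 - level) / 2
  unname(diff(stats::quantile(estimates, c(a, 1 - a), type = 7)))
}

# Summarize a replicate ledger (tibble: parameter, method, fmi, status,
# converged) against pseudo-population values. Exposed for testing.
summarize_replicates <- function(replicates, delta_pop, n_rep) {
  dplyr::left_join(replicates, delta_pop, by = "parameter") |>
    dplyr::group_by(.data$parameter, .data$method) |>
    dplyr::summarise(
      delta_pop = .data$delta_pop[1L],
      n_ok = sum(.data$status == "ok"),
      n_negative = sum(.data$status == "negative"),
      n_undefined = sum(.data$status == "undefined" & .data$converged),
      n_nonconverged = sum(!.data$converged),
      mean_fmi = mean(.data$fmi[.data$status == "ok"]),
      bias = if (any(.data$status == "ok"))
        bias_fmi(.data$fmi[.data$status == "ok"], .data$delta_pop[1L])
      else NA_real_,
      rmse = if (any(.data$status == "ok"))
        rmse_fmi(.data$fmi[.data$status == "ok"], .data$delta_pop[1L])
      else NA_real_,
      eti_width = if (sum(.data$status == "ok") >= 2L)
        eti_width(.data$fmi[.data$status == "ok"])
      else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(n_rep = n_rep)
}

#' Run one Monte-Carlo condition
#'
#' Simulates `n_rep` independent datasets (replicate `i` uses master seed
#' `base_seed + i`), estimates the FMI of every parameter under each
#' requested variant, classifies failures (non-converged fit: all parameters
#' undefined; converged with non-positive-definite information: undefined;
#' negative FMI: improper), and summarizes bias, RMSE and 95% ETI width over
#' the valid (`status = "ok"`) replicates only.
#'
#' @param condition An [`simulation_condition()`].
#' @param delta_pop Optional tibble `parameter`, `delta_pop`; computed from a
#'   fresh pseudo-population run when absent.
#' @param pop_seed Seed for the pseudo-population run (default derived from
#'   the condition's base seed).
#' @param keep_replicates Keep the per-replicate FMI draws (default `TRUE`).
#' @return A list of class `fmi_condition_summary`: `condition`, `delta_pop`,
#'   `summary` (tibble per parameter and method), `replicates`.
#' @export
run_condition <- function(condition, delta_pop = NULL, pop_seed = NULL,
                          keep_replicates = TRUE) {
  stopifnot(inherits(condition, "fmi_condition"))
  model <- pop_model_for(condition$population)
  mech <- mechanism_for(condition$population, condition$mechanism,
                        condition$pi_mis)
  if (is.null(delta_pop)) {
    pop_seed <- pop_seed %||% substream_seed(condition$base_seed, 777L)
    delta_pop <- pseudo_population_fmi(condition$population, mech,
                                       seed = pop_seed)
  }
  reps <- purrr::map_dfr(seq_len(condition$n_rep), function(i) {
    dat <- simulate_dataset(condition$population, condition$n, mech,
                            condition$base_seed + i)
    tab <- compute_fmi(dat, model, methods = condition$methods)
    fit <- attr(tab, "fit")
    tibble::as_tibble(tab)[, c("parameter", "method", "fmi", "status")] |>
      dplyr::mutate(replicate = i, converged = fit$converged)
  })
  summ <- summarize_replicates(reps, delta_pop, condition$n_rep)
  structure(list(condition = condition, delta_pop = delta_pop,
                 summary = summ,
                 replicates = if (keep_replicates) reps else NULL),
            class = "fmi_condition_summary")
}

#' @export
print.fmi_condition_summary <- function(x, ...) {
  cond <- x$condition
  cat(sprintf("<fmi_condition_summary> %s / %s / pi_mis = %.1f / N = %d / %d reps\n",
              cond$population, cond$mechanism, cond$pi_mis, cond$n, cond$n_rep))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname run_condition
#' @param x An `fmi_condition_summary`.
#' @param ... Unused.
#' @export
tidy.fmi_condition_summary <- function(x, ...) x$summary

#' Density plot of Monte-Carlo FMI draws
#'
#' Smoothed sampling distributions of the FMI estimates for one condition,
#' one panel per parameter, with the pseudo-population value as a dashed
#' vertical line.
#'
#' @param object An `fmi_condition_summary` with retained replicates.
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fmi_condition_summary <- function(object, parameters = NULL, ...) {
  reps <- object$replicates
  if (is.null(reps))
    abort_fmi("replicates were not retained", "fmitools_config_error")
  if (!is.null(parameters))
    reps <- dplyr::filter(reps, .data$parameter %in% parameters)
  ok <- dplyr::filter(reps, .data$status == "ok")
  dp <- object$delta_pop
  if (!is.null(parameters))
    dp <- dplyr::filter(dp, .data$parameter %in% parameters)
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$fmi, colour = .data$method)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(data = dp,
                        ggplot2::aes(xintercept = .data$delta_pop),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "FMI estimate", y = "density", colour = "estimator")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
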