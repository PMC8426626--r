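#' Width inflation factor
#'
#' Converts a fraction of missing information into the multiplicative
#' inflation of the standard error (and confidence-interval width) relative
#' to complete data: `WIF = 1 / sqrt(1 - delta)`. An FMI of 0.75 doubles the
#' standard error.
#'
#' @param delta Numeric vector of FMI values in `[0, 1)`.
#' @return Numeric vector of width inflation factors (all `>= 1`).
#' @examples
#' wif(c(0, 0.5, 0.75))
#' @export
wif <- function(delta) {
  if (any(!is.finite(delta)) || any(delta < 0) || any(delta >= 1))
    abort_fmi("delta must lie in [0, 1)", "fmitools_domain_error")
  1 / sqrt(1 - delta)
}

#' Per-parameter FMI from an information pair
#'
#' Given observed-data and complete-data information matrices of the same
#' dimension, computes for each parameter
#' `delta_j = 1 - (J_X^-1)_jj / (J_Y^-1)_jj`, the observed and complete
#' standard errors, and the width inflation factor. Negative estimates are
#' retained with `status = "negative"` (improper, excluded from
#' aggregation); if either matrix is not positive definite every parameter
#' is `status = "undefined"`.
#'
#' @param J_Y Observed-data information (`fmi_info` or plain matrix).
#' @param J_X Complete-data information of the same dimension.
#' @param parameters Optional parameter names.
#' @param method Label recorded in the output (e.g. `"delta1"`).
#' @return A tibble: `parameter`, `se_observed`, `se_complete`, `fmi`,
#'   `wif`, `status`.
#' @export
fmi_from_info <- function(J_Y, J_X, parameters = NULL, method = NA_character_) {
  if (!all(dim(J_Y) == dim(J_X)))
    abort_fmi("information matrices have mismatched dimensions",
              "fmitools_contract_error")
  q <- nrow(J_Y)
  pars <- parameters %||% rownames(J_Y) %||% paste0("theta", seq_len(q))
  undef <- tibble::tibble(parameter = pars, method = method,
                          se_observed = NA_real_, se_complete = NA_real_,
                          fmi = NA_real_, wif = NA_real_,
                          status = "undefined")
  vY <- tryCatch(diag(chol2inv(chol(unclass(J_Y)))), error = function(e) NULL)
  vX <- tryCatch(diag(chol2inv(chol(unclass(J_X)))), error = function(e) NULL)
  if (is.null(vY) || is.null(vX) || any(!is.finite(c(vY, vX))))
    return(undef)
  delta <- 1 - vX / vY
  status <- dplyr::case_when(
    !is.finite(delta) | delta >= 1 ~ "undefined",
    delta < 0 ~ "negative",
    TRUE ~ "ok"
  )
  tibble::tibble(
    parameter = pars,
    method = method,
    se_observed = sqrt(pmax(vY, 0)),
    se_complete = sqrt(pmax(vX, 0)),
    fmi = ifelse(status == "undefined", NA_real_, delta),
    wif = ifelse(status == "ok", 1 / sqrt(1 - delta), NA_real_),
    status = status
  )
}

fmi_method_labels <- c(delta1 = "delta1_hessian",
                       delta2 = "delta2_structured",
                       delta3 = "delta3_unstructured")

#' Fraction of missing information from incomplete data
#'
#' End-to-end FMI estimation: partitions the data into missingness patterns,
#' fits the structured model by FIML, and for each requested variant builds
#' the observed- and complete-data information and the per-parameter FMI.
#' The three variants are `"delta1"` (numeric Hessian on both sides),
#' `"delta2"` (analytic first-dominant-term information at the model-implied
#' moments) and `"delta3"` (same analytic form at the unstructured EM
#' moments). They coincide on saturated models such as the regression path
#' model.
#'
#' A non-converged FIML fit yields a table of `status = "undefined"` rows
#' rather than an error, so simulation loops can account for failures.
#'
#' @param data A data frame with `NA` missing cells, or an
#'   [`fmi_patterns`] object.
#' @param model An [`fmi_model`].
#' @param methods Subset of `c("delta1", "delta2", "delta3")`.
#' @param control Passed to [fit_fiml()].
#' @return A tibble with one row per parameter and method: `parameter`,
#'   `method`, `estimate`, `se_observed`, `se_complete`, `fmi`, `wif`,
#'   `status`. The `fiml_fit` and (if computed) `saturated_fit` are attached
#'   as attributes `"fit"` and `"saturated_fit"`.
#' @examples
#' d <- simulate_regression_population(300, seed = 5)
#' mech <- regression_mechanism("mcar", pi_mis = 0.2)
#' obs <- impose_missingness(d, mech, seed = 6)
#' compute_fmi(obs, regression_model(), methods = "delta2")
#' @export
compute_fmi <- function(data, model,
                        methods = c("delta1", "delta2", "delta3"),
                        control = list()) {
  methods <- match.arg(methods, several.ok = TRUE)
  pats <- as_patterns(data)
  fit <- fit_fiml(pats, model, control = control)
  sat <- NULL
  if ("delta3" %in% methods)
    sat <- fit_saturated_em(pats)
  res <- purrr::map_dfr(methods, function(m) {
    label <- fmi_method_labels[[m]]
    if (!fit$converged || (m == "delta3" && !sat$converged)) {
      tab <- tibble::tibble(parameter = model$par_names, method = label,
                            se_observed = NA_real_, se_complete = NA_real_,
                            fmi = NA_real_, wif = NA_real_,
                            status = "undefined")
      return(tab)
    }
    info <- tryCatch(switch(m,
      delta1 = list(Y = observed_info_hessian(fit),
                    X = complete_info(fit, "hessian")),
      delta2 = list(Y = observed_info_analytic(fit, "implied"),
                    X = complete_info(fit, "analytic_structured")),
      delta3 = list(Y = observed_info_analytic(fit, "saturated_em",
                                               saturated_fit = sat),
                    X = complete_info(fit, "analytic_unstructured",
                                      saturated_fit = sat))
    ), error = function(e) NULL)
    if (is.null(info)) {
      return(tibble::tibble(parameter = model$par_names, method = label,
                            se_observed = NA_real_, se_complete = NA_real_,
                            fmi = NA_real_, wif = NA_real_,
                            status = "undefined"))
    }
    if (!attr(info$Y, "pos_def") || !attr(info$X, "pos_def")) {
      return(tibble::tibble(parameter = model$par_names, method = label,
                            se_observed = NA_real_, se_complete = NA_real_,
                            fmi = NA_real_, wif = NA_real_,
                            status = "undefined"))
    }
    fmi_from_info(info$Y, info$X, model$par_names, method = label)
  })
  res <- dplyr::left_join(
    res,
    tibble::tibble(parameter = model$par_names, estimate = unname(fit$theta)),
    by = "parameter")
  res <- dplyr::relocate(res, "parameter", "method", "estimate")
  attr(res, "fit") <- fit
  attr(res, "saturated_fit") <- sat
  class(res) <- c("fmi_tbl", class(res))
  res
}

#' Write an FMI table to disk
#'
#' Writes the parameter table produced by [compute_fmi()] as CSV and,
#' optionally, JSON.
#'
#' @param fmi_table Output of [compute_fmi()].
#' @param path CSV output path.
#' @param json_path Optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_fmi_table <- function(fmi_table, path, json_path = NULL) {
  tab <- tibble::as_tibble(fmi_table)
  readr::write_csv(tab, path)
  if (!is.null(json_path))
    jsonlite::write_json(tab, json_path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
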