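#' Mean-and-covariance structure models
#'
#' A model specification maps a free-parameter vector \eqn{\theta} (length
#' \eqn{q}) to model-implied moments \eqn{\mu(\theta)} (length \eqn{p}) and
#' \eqn{\Sigma(\theta)} (\eqn{p \times p}). Three families are supported:
#' the saturated (unstructured) model whose parameters are the moments
#' themselves, a bivariate regression path model, and single-level
#' confirmatory factor analysis with latent variances fixed to 1 (std.lv
#' identification) so that all loadings are free.
#'
#' @name fmi_model
#' @keywords internal
NULL

new_fmi_model <- function(kind, var_names, par_names, par_roles, moments_fn,
                          extra = list()) {
  stopifnot(length(par_names) == length(par_roles))
  structure(
    c(list(
      kind = kind,
      p = length(var_names),
      q = length(par_names),
      var_names = var_names,
      par_names = par_names,
      par_roles = par_roles,
      moments_fn = moments_fn
    ), extra),
    class = "fmi_model"
  )
}

#' @export
print.fmi_model <- function(x, ...) {
  cat("<fmi_model> kind =", x$kind,
      "| p =", x$p, "observed variables | q =", x$q, "free parameters\n")
  cat("variables:", paste(x$var_names, collapse = ", "), "\n")
  invisible(x)
}

#' Bivariate regression path model
#'
#' The path model `Y = alpha + beta * X + E` treated as a mean-and-covariance
#' structure with five free parameters: the mean and variance of `X`
#' (`mu_x`, `phi_x`), the intercept `alpha`, the slope `beta`, and the
#' residual variance `psi`. The model is saturated for two variables
#' (`q = 5` equals the number of first and second moments), so its degrees of
#' freedom are zero and the three FMI estimators coincide on it.
#'
#' Implied moments: `mu = (mu_x, alpha + beta * mu_x)` and
#' `Sigma = [[phi_x, beta * phi_x], [beta * phi_x, beta^2 * phi_x + psi]]`.
#'
#' @param var_names Names of the two observed variables (predictor first).
#' @return An `fmi_model` object.
#' @examples
#' m <- regression_model()
#' implied_moments(m, c(0, 1, 0, 0.4, 0.84))
#' @export
regression_model <- function(var_names = c("X", "Y")) {
  stopifnot(length(var_names) == 2L)
  new_fmi_model(
    kind = "regression",
    var_names = var_names,
    par_names = c("mu_x", "phi_x", "alpha", "beta", "psi"),
    par_roles = c("mean", "variance", "intercept", "regression_slope",
                  "variance"),
    moments_fn = function(theta) {
      mu_x <- theta[1L]; phi_x <- theta[2L]; alpha <- theta[3L]
      beta <- theta[4L]; psi <- theta[5L]
      mu <- c(mu_x, alpha + beta * mu_x)
      sigma <- matrix(c(phi_x, beta * phi_x,
                        beta * phi_x, beta^2 * phi_x + psi), 2L, 2L)
      list(mu = mu, sigma = sigma)
    }
  )
}

#' Single-level confirmatory factor analysis model
#'
#' Builds a CFA with simple structure from a factor-to-indicator map, using
#' std.lv identification: latent variances are fixed to 1, latent covariances
#' (correlations) are free, all loadings are free, all error variances are
#' free, all indicator means are free. Implied moments are
#' `Sigma = Lambda Phi Lambda' + Theta` (Theta diagonal) and the free means.
#'
#' The factor map is given either as a named list
#' (`list(F1 = c("X1","X2"), ...)`) or as character lines in the compact
#' syntax `"F1 =~ X1 + X2"`.
#'
#' @param factors Named list or character vector of `=~` lines.
#' @return An `fmi_model` object.
#' @examples
#' cfa_model(c("F1 =~ X1 + X2 + X3", "F2 =~ Y1 + Y2 + Y3"))
#' @export
cfa_model <- function(factors) {
  fmap <- parse_factor_map(factors)
  fac_names <- names(fmap)
  k <- length(fmap)
  vars <- unname(unlist(fmap))
  if (anyDuplicated(vars) > 0L)
    abort_fmi("each indicator may load on exactly one factor (simple structure)",
              "fmitools_model_error")
  p <- length(vars)

  load_names <- paste0("lambda_", vars)
  corr_pairs <- if (k > 1L) utils::combn(k, 2L) else matrix(0L, 2L, 0L)
  corr_names <- if (ncol(corr_pairs))
    paste0("phi_", fac_names[corr_pairs[1L, ]], ".", fac_names[corr_pairs[2L, ]])
  else character()
  err_names <- paste0("theta_", vars)
  mean_names <- paste0("mu_", vars)

  # loading pattern: row = indicator, col = factor
  Lpat <- matrix(0L, p, k, dimnames = list(vars, fac_names))
  for (f in fac_names) Lpat[fmap[[f]], f] <- 1L
  n_load <- p
  n_corr <- ncol(corr_pairs)

  moments_fn <- function(theta) {
    lam <- theta[seq_len(n_load)]
    phi <- if (n_corr) theta[n_load + seq_len(n_corr)] else numeric()
    errv <- theta[n_load + n_corr + seq_len(p)]
    mu <- theta[n_load + n_corr + p + seq_len(p)]
    Lambda <- Lpat * lam            # simple structure: one loading per row
    Phi <- diag(1, k)
    if (n_corr) {
      for (m in seq_len(n_corr)) {
        i <- corr_pairs[1L, m]; j <- corr_pairs[2L, m]
        Phi[i, j] <- Phi[j, i] <- phi[m]
      }
    }
    sigma <- Lambda %*% Phi %*% t(Lambda)
    diag(sigma) <- diag(sigma) + errv
    list(mu = mu, sigma = symmetrize(sigma))
  }

  new_fmi_model(
    kind = "cfa",
    var_names = vars,
    par_names = c(load_names, corr_names, err_names, mean_names),
    par_roles = c(rep("loading", n_load), rep("factor_cov", n_corr),
                  rep("error_var", p), rep("mean", p)),
    moments_fn = moments_fn,
    extra = list(factor_map = fmap, identification = "std_lv")
  )
}

parse_factor_map <- function(factors) {
  if (is.list(factors)) {
    stopifnot(!is.null(names(factors)))
    return(lapply(factors, as.character))
  }
  stopifnot(is.character(factors))
  fmap <- list()
  for (line in factors) {
    parts <- strsplit(line, "=~", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      abort_fmi(paste0("cannot parse factor block: '", line, "'"),
                "fmitools_model_error")
    fac <- trimws(parts[1L])
    inds <- trimws(strsplit(parts[2L], "+", fixed = TRUE)[[1L]])
    inds <- inds[nzchar(inds)]
    if (!nzchar(fac) || length(inds) == 0L)
      abort_fmi(paste0("cannot parse factor block: '", line, "'"),
                "fmitools_model_error")
    fmap[[fac]] <- inds
  }
  fmap
}

#' Two-factor model with four indicators per factor
#'
#' The eight-indicator, two-factor CFA used throughout the simulation designs:
#' `X1..X4` load on `F1`, `Y1..Y4` on `F2`, std.lv identification. Free
#' parameters: 8 loadings, 1 factor correlation, 8 error variances, 8 means
#' (`q = 25`, 19 degrees of freedom).
#'
#' @return An `fmi_model` object.
#' @export
two_factor_model <- function() {
  cfa_model(c("F1 =~ X1 + X2 + X3 + X4", "F2 =~ Y1 + Y2 + Y3 + Y4"))
}

#' Saturated (unstructured) model
#'
#' The unrestricted multivariate-normal mean and covariance: the parameter
#' vector is `(mu_1..mu_p, vech(Sigma))` with vech taken lower-triangular,
#' column-major, diagonal included, so `q = p + p(p+1)/2` and the implied
#' moments are the parameters themselves. This is the h1 model whose EM
#' estimates feed the analytic-unstructured FMI variant.
#'
#' @param p Number of observed variables (>= 1).
#' @param var_names Optional variable names (default `V1..Vp`).
#' @return An `fmi_model` object.
#' @export
saturated_model <- function(p, var_names = NULL) {
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p))
    abort_fmi("p must be a positive integer", "fmitools_dimension_error")
  p <- as.integer(p)
  vars <- var_names %||% paste0("V", seq_len(p))
  stopifnot(length(vars) == p)
  vn <- vech_names(vars)
  vi <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  diag_pos <- which(vi[order(vi[, 2L], vi[, 1L]), 1L] ==
                    vi[order(vi[, 2L], vi[, 1L]), 2L])
  roles <- rep("covariance", length(vn))
  roles[diag_pos] <- "variance"
  new_fmi_model(
    kind = "saturated",
    var_names = vars,
    par_names = c(paste0("mu_", vars), vn),
    par_roles = c(rep("mean", p), roles),
    moments_fn = function(theta) {
      list(mu = theta[seq_len(p)], sigma = unvech(theta[-seq_len(p)], p))
    }
  )
}

#' Model-implied moments
#'
#' Evaluates \eqn{\mu(\theta)} and \eqn{\Sigma(\theta)} for a model at a
#' parameter vector, with an admissibility check on the implied covariance
#' matrix.
#'
#' @param model An [`fmi_model`].
#' @param theta Numeric vector of length `model$q`.
#' @param check_pd Check positive definiteness of the implied covariance
#'   (default `TRUE`); the error carries the smallest eigenvalue.
#' @return List with elements `mu`, `sigma`, `source = "implied"`.
#' @export
implied_moments <- function(model, theta, check_pd = TRUE) {
  stopifnot(inherits(model, "fmi_model"))
  if (length(theta) != model$q)
    abort_fmi(sprintf("theta has length %d, expected q = %d",
                      length(theta), model$q), "fmitools_dimension_error")
  mm <- model$moments_fn(as.numeric(theta))
  mm$sigma <- symmetrize(mm$sigma)
  if (check_pd) {
    ev <- min(eigen(mm$sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      abort_fmi(sprintf("implied covariance is not positive definite (min eigenvalue %.3e)", ev),
                "fmitools_inadmissible_moments")
  }
  mm$source <- "implied"
  names(mm$mu) <- model$var_names
  dimnames(mm$sigma) <- list(model$var_names, model$var_names)
  mm
}

#' Jacobian of the stacked moment vector
#'
#' Central-finite-difference Jacobian of `(mu(theta), vech(Sigma(theta)))`
#' with respect to `theta`; rows are ordered means first, then vech in
#' lower-triangular column-major order. Per-coordinate step
#' `h_j = 1e-5 * max(1, |theta_j|)`. This is the Delta matrix that sandwiches
#' the unstructured information in the analytic FMI variants; for the
#' saturated model it is exactly the identity.
#'
#' @inheritParams implied_moments
#' @return A `(p + p(p+1)/2) x q` matrix.
#' @export
model_jacobian <- function(model, theta) {
  stopifnot(inherits(model, "fmi_model"))
  theta <- as.numeric(theta)
  if (length(theta) != model$q)
    abort_fmi("theta has wrong length", "fmitools_dimension_error")
  if (model$kind == "saturated") {
    # parameters ARE the moments: exact identity, bit-for-bit
    J <- diag(1, model$q)
    rownames(J) <- colnames(J) <- model$par_names
    return(J)
  }
  stack <- function(th) {
    mm <- model$moments_fn(th)
    c(mm$mu, vech(symmetrize(mm$sigma)))
  }
  d <- model$p + model$p * (model$p + 1L) / 2L
  J <- matrix(0, d, model$q)
  for (j in seq_len(model$q)) {
    h <- 1e-5 * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (stack(tp) - stack(tm)) / (2 * h)
  }
  rownames(J) <- c(paste0("mu_", model$var_names), vech_names(model$var_names))
  colnames(J) <- model$par_names
  J
}
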