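# Observed- and complete-data information matrices under the three
# computational variants. All matrices are on the total-sample scale (summed
# over the N cases), so SE_j = sqrt{(J^-1)_jj} directly.

new_fmi_info <- function(matrix, method, side, moment_source, par_names) {
  m <- symmetrize(matrix)
  dimnames(m) <- list(par_names, par_names)
  structure(m, class = c("fmi_info", "matrix"),
            method = method, side = side, moment_source = moment_source,
            pos_def = is_pos_def(m))
}

#' @export
print.fmi_info <- function(x, ...) {
  cat("<fmi_info>", attr(x, "method"), "|", attr(x, "side"),
      "| moments:", attr(x, "moment_source"),
      "| PD:", attr(x, "pos_def"), "\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Central-difference numeric Hessian
#'
#' Second-derivative matrix of a scalar function by central differences with
#' per-coordinate step `h_j = h_scale * max(1, |x0_j|)`, symmetrized as
#' `(H + H')/2`.
#'
#' @param f Scalar function of a numeric vector.
#' @param x0 Evaluation point.
#' @param h_scale Relative step size (default `1e-4`).
#' @return A symmetric matrix.
#' @export
numeric_hessian <- function(f, x0, h_scale = 1e-4) {
  x0 <- as.numeric(x0)
  q <- length(x0)
  h <- h_scale * pmax(1, abs(x0))
  f0 <- f(x0)
  ev <- function(x, what) {
    v <- f(x)
    if (!is.finite(v))
      abort_fmi(paste0("non-finite function value at stencil point (", what, ")"),
                "fmitools_differentiation_error")
    v
  }
  if (!is.finite(f0))
    abort_fmi("non-finite function value at the expansion point",
              "fmitools_differentiation_error")
  H <- matrix(0, q, q)
  fp <- numeric(q); fm <- numeric(q)
  for (j in seq_len(q)) {
    xp <- x0; xp[j] <- xp[j] + h[j]
    xm <- x0; xm[j] <- xm[j] - h[j]
    fp[j] <- ev(xp, paste0("coordinate ", j, " +"))
    fm[j] <- ev(xm, paste0("coordinate ", j, " -"))
    H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h[j]^2
  }
  if (q > 1L) {
    for (j in seq_len(q - 1L)) {
      for (k in (j + 1L):q) {
        xpp <- x0; xpp[j] <- xpp[j] + h[j]; xpp[k] <- xpp[k] + h[k]
        xpm <- x0; xpm[j] <- xpm[j] + h[j]; xpm[k] <- xpm[k] - h[k]
        xmp <- x0; xmp[j] <- xmp[j] - h[j]; xmp[k] <- xmp[k] + h[k]
        xmm <- x0; xmm[j] <- xmm[j] - h[j]; xmm[k] <- xmm[k] - h[k]
        H[j, k] <- H[k, j] <-
          (ev(xpp, "++") - ev(xpm, "+-") - ev(xmp, "-+") + ev(xmm, "--")) /
          (4 * h[j] * h[k])
      }
    }
  }
  symmetrize(H)
}

#' Observed information from the numeric Hessian
#'
#' The negative central-difference Hessian of the observed-data
#' log-likelihood at the FIML estimate, on the untransformed parameter scale.
#' A non-positive-definite result is flagged (attribute `pos_def`), not
#' raised, so a simulation replicate can be classified as failed downstream.
#'
#' @param fit An [`fiml_fit`] (or pass `model`, `theta`, `patterns` via a
#'   fitted object).
#' @param patterns Optional `fmi_patterns`; defaults to the fit's own.
#' @return An `fmi_info` matrix (`method = "hessian"`, `side = "observed_Y"`).
#' @export
observed_info_hessian <- function(fit, patterns = NULL) {
  stopifnot(inherits(fit, "fiml_fit"))
  pats <- patterns %||% fit$patterns
  f <- function(th) {
    tryCatch(observed_loglik(fit$model, th, pats), error = function(e) NA_real_)
  }
  H <- numeric_hessian(f, fit$theta)
  new_fmi_info(-H, "hessian", "observed_Y", "implied", fit$model$par_names)
}

# Analytic score (gradient) of the observed-data log-likelihood with respect
# to the unstructured parameters (mu, vech Sigma), accumulated per pattern:
#   d l / d mu        = sum_g n_g A d
#   d l / d vech(Sig) = sum_g (n_g/2) D' vec(A T A - A)
# with A = Sigma_g^{-1}, d = xbar_g - mu_g, T = S_g + d d'.
h1_score <- function(moments, pats) {
  p <- pats$p
  mu <- as.numeric(moments$mu)
  Sigma <- unname(as.matrix(moments$sigma))
  g <- numeric(p + p * (p + 1L) / 2L)
  VI <- vech_index_matrix(p)
  dup_cache <- list()
  for (pt in pats$patterns) {
    O <- pt$idx
    pg <- length(O)
    key <- as.character(pg)
    D <- dup_cache[[key]]
    if (is.null(D)) {
      D <- duplication_matrix(pg)
      dup_cache[[key]] <- D
    }
    A <- chol2inv(chol(Sigma[O, O, drop = FALSE]))
    d <- pt$xbar - mu[O]
    Tm <- pt$S + tcrossprod(d)
    g[O] <- g[O] + pt$n * as.vector(A %*% d)
    vloc <- VI[O, O, drop = FALSE]
    vmap <- p + vloc[lower.tri(vloc, diag = TRUE)]
    g[vmap] <- g[vmap] +
      (pt$n / 2) * as.vector(t(D) %*% as.vector(A %*% Tm %*% A - A))
  }
  g
}

# Score with respect to the structured parameters via the model Jacobian.
model_score <- function(model, theta, pats) {
  mm <- model$moments_fn(as.numeric(theta))
  g <- h1_score(mm, pats)
  if (model$kind == "saturated") return(g)
  as.vector(t(model_jacobian(model, theta)) %*% g)
}

# Analytic observed information of the unstructured parameters (mu, vech
# Sigma), accumulated per pattern from the sufficient statistics, evaluated at
# arbitrary admissible moments. With A = Sigma_g^{-1}, d = xbar - mu_g,
# T = S_g + d d':
#   mean block            n A
#   mean-cov cross block  n (d'A (x) A) D
#   cov block             (n/2) D' [ATA (x) A + A (x) ATA - A (x) A] D
# each embedded into full (mu, vech Sigma) coordinates. By construction this
# equals the negative Hessian of the saturated observed log-likelihood.

#' Analytic unstructured observed information
#'
#' Observed information of the saturated parameters `(mu, vech Sigma)` for
#' incomplete data, built pattern-by-pattern in closed form at the supplied
#' moments. Equals the negative numeric Hessian of [observed_loglik()] for
#' the saturated model evaluated at the same moments.
#'
#' @param moments List with `mu`, `sigma` (e.g. from [fit_saturated_em()] or
#'   [implied_moments()]).
#' @param patterns An [`fmi_patterns`] object.
#' @return A symmetric `(p + p(p+1)/2)` square matrix.
#' @export
h1_observed_info <- function(moments, patterns) {
  pats <- as_patterns(patterns)
  p <- pats$p
  mu <- as.numeric(moments$mu)
  Sigma <- unname(as.matrix(moments$sigma))
  stopifnot(length(mu) == p)
  d_full <- p + p * (p + 1L) / 2L
  J <- matrix(0, d_full, d_full)
  VI <- vech_index_matrix(p)
  dup_cache <- list()
  for (pt in pats$patterns) {
    O <- pt$idx
    pg <- length(O)
    key <- as.character(pg)
    D <- dup_cache[[key]]
    if (is.null(D)) {
      D <- duplication_matrix(pg)
      dup_cache[[key]] <- D
    }
    Sg <- Sigma[O, O, drop = FALSE]
    A <- tryCatch(chol2inv(chol(Sg)), error = function(e)
      abort_fmi("singular covariance submatrix in information construction",
                "fmitools_information_error"))
    d <- pt$xbar - mu[O]
    Tm <- pt$S + tcrossprod(d)
    ATA <- A %*% Tm %*% A
    n <- pt$n
    I_mm <- n * A
    I_ms <- n * (t(d) %*% A %x% A) %*% D          # pg x pg(pg+1)/2
    I_ss <- (n / 2) * t(D) %*% (ATA %x% A + A %x% ATA - A %x% A) %*% D
    # embed
    vloc <- VI[O, O, drop = FALSE]
    vmap <- p + vloc[lower.tri(vloc, diag = TRUE)]
    map <- c(O, vmap)
    blk <- rbind(cbind(I_mm, I_ms), cbind(t(I_ms), I_ss))
    J[map, map] <- J[map, map] + blk
  }
  symmetrize(J)
}

#' Analytic observed information for a structured model
#'
#' The first-dominant-term approximation: the unstructured observed
#' information evaluated at moments `M`, sandwiched between the model
#' Jacobians, `J = Delta' H1(M) Delta`. For `moment_source = "implied"`
#' (the structured variant) `M = mu(theta), Sigma(theta)` at the FIML
#' estimate; for `moment_source = "saturated_em"` (the unstructured variant)
#' `M` is the EM saturated estimate.
#'
#' @param fit An [`fiml_fit`].
#' @param moment_source `"implied"` or `"saturated_em"`.
#' @param saturated_fit A [`fit_saturated_em()`] result; required when
#'   `moment_source = "saturated_em"`.
#' @param patterns Optional override of the fit's pattern set.
#' @return An `fmi_info` matrix (`side = "observed_Y"`).
#' @export
observed_info_analytic <- function(fit, moment_source = c("implied", "saturated_em"),
                                   saturated_fit = NULL, patterns = NULL) {
  stopifnot(inherits(fit, "fiml_fit"))
  moment_source <- match.arg(moment_source)
  pats <- patterns %||% fit$patterns
  M <- if (moment_source == "implied") {
    implied_moments(fit$model, fit$theta, check_pd = FALSE)
  } else {
    if (is.null(saturated_fit))
      abort_fmi("saturated_fit is required for moment_source = 'saturated_em'",
                "fmitools_config_error")
    saturated_fit$moments
  }
  H1 <- h1_observed_info(M, pats)
  Delta <- model_jacobian(fit$model, fit$theta)
  method <- if (moment_source == "implied") "analytic_structured"
            else "analytic_unstructured"
  new_fmi_info(t(Delta) %*% H1 %*% Delta, method, "observed_Y",
               moment_source, fit$model$par_names)
}

#' Complete-data information at the FIML estimate
#'
#' Estimates what the information (and hence standard errors) would have been
#' with no missing data, by treating a pseudo-sample of size `N` whose sample
#' moments are held fixed at `M`: the implied moments at the FIML estimate
#' for the hessian and analytic-structured variants, or the EM saturated
#' moments for the analytic-unstructured variant. `method = "hessian"` takes
#' the negative numeric Hessian of that complete-data log-likelihood at the
#' estimate; the analytic methods use the single-pattern unstructured
#' information at `M` sandwiched by the model Jacobian.
#'
#' @param fit An [`fiml_fit`].
#' @param method `"hessian"`, `"analytic_structured"` or
#'   `"analytic_unstructured"`.
#' @param saturated_fit Required for `"analytic_unstructured"`.
#' @param N Pseudo-sample size; defaults to the fitted sample size.
#' @return An `fmi_info` matrix (`side = "complete_X"`).
#' @export
complete_info <- function(fit,
                          method = c("hessian", "analytic_structured",
                                     "analytic_unstructured"),
                          saturated_fit = NULL, N = NULL) {
  stopifnot(inherits(fit, "fiml_fit"))
  method <- match.arg(method)
  N <- N %||% fit$N
  moment_source <- if (method == "analytic_unstructured") "saturated_em"
                   else "implied"
  M <- if (moment_source == "implied") {
    implied_moments(fit$model, fit$theta, check_pd = FALSE)
  } else {
    if (is.null(saturated_fit))
      abort_fmi("saturated_fit is required for the unstructured variant",
                "fmitools_config_error")
    saturated_fit$moments
  }
  pseudo <- complete_pattern_set(M$mu, M$sigma, N, fit$model$var_names)
  if (method == "hessian") {
    f <- function(th) {
      tryCatch(observed_loglik(fit$model, th, pseudo),
               error = function(e) NA_real_)
    }
    H <- numeric_hessian(f, fit$theta)
    return(new_fmi_info(-H, method, "complete_X", moment_source,
                        fit$model$par_names))
  }
  H1 <- h1_observed_info(M, pseudo)
  Delta <- model_jacobian(fit$model, fit$theta)
  new_fmi_info(t(Delta) %*% H1 %*% Delta, method, "complete_X", moment_source,
               fit$model$par_names)
}

#' Export an information matrix to CSV
#'
#' @param info An `fmi_info` matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_info_csv <- function(info, path) {
  df <- as.data.frame(unclass(info))
  df <- cbind(parameter = rownames(info), df)
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}
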