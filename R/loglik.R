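#' Observed-data log-likelihood
#'
#' The multivariate-normal observed-data (FIML) log-likelihood, accumulated
#' over missingness patterns. Each pattern `g` with `n_g` cases, observed
#' index set `O_g`, mean `xbar_g` and ML covariance `S_g` contributes
#' \deqn{n_g\left[-\tfrac{p_g}{2}\log 2\pi - \tfrac12 \log|\Sigma_g|
#'   - \tfrac12 \mathrm{tr}\{\Sigma_g^{-1}(S_g + d_g d_g')\}\right]}
#' with \eqn{d_g = \bar x_g - \mu_g} and \eqn{\mu_g,\Sigma_g} the pattern
#' subvector/submatrix of the model-implied moments. This equals the case-wise
#' sum of per-case normal log-densities over the observed entries.
#'
#' @param model An [`fmi_model`].
#' @param theta Parameter vector (length `model$q`).
#' @param patterns An `fmi_patterns` object (or raw data, which is
#'   partitioned on the fly).
#' @return The total-sample log-likelihood (a scalar).
#' @export
observed_loglik <- function(model, theta, patterns) {
  pats <- as_patterns(patterns)
  stopifnot(inherits(model, "fmi_model"), pats$p == model$p)
  mm <- model$moments_fn(as.numeric(theta))
  mu <- mm$mu
  sigma <- symmetrize(mm$sigma)
  ll <- 0
  for (pt in pats$patterns) {
    sg <- sigma[pt$idx, pt$idx, drop = FALSE]
    R <- tryCatch(chol(sg), error = function(e)
      abort_fmi("singular or non-PD covariance submatrix in a missingness pattern",
                "fmitools_loglik_error"))
    d <- pt$xbar - mu[pt$idx]
    W <- pt$S + tcrossprod(d)
    ld <- 2 * sum(log(diag(R)))
    tr <- sum(chol2inv(R) * W)
    ll <- ll + pt$n * (-0.5 * length(pt$idx) * log(2 * pi) - 0.5 * ld - 0.5 * tr)
  }
  ll
}
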