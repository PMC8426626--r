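# Available-case means and a diagonal covariance (always PD): the EM start
# and the fallback start for structured fits when EM itself fails.
available_case_moments <- function(pats) {
  p <- pats$p
  mu <- numeric(p)
  v <- rep(1, p)
  for (j in seq_len(p)) {
    tot <- 0; cnt <- 0; totsq <- 0
    for (pt in pats$patterns) {
      k <- match(j, pt$idx)
      if (!is.na(k)) {
        tot <- tot + pt$n * pt$xbar[k]
        totsq <- totsq + pt$n * (pt$S[k, k] + pt$xbar[k]^2)
        cnt <- cnt + pt$n
      }
    }
    if (cnt > 0L) {
      mu[j] <- tot / cnt
      v[j] <- max(totsq / cnt - mu[j]^2, 1e-8)
    }
  }
  list(mu = mu, sigma = diag(v, p))
}

#' Saturated (unstructured) estimation by EM
#'
#' Estimates the unrestricted multivariate-normal mean vector and covariance
#' matrix from incomplete data by expectation-maximization, working entirely
#' on the per-pattern sufficient statistics. The E-step fills in, for each
#' missingness pattern, the conditional expectations of the missing block
#' given the observed block under the current moments; the M-step is the
#' complete-data ML update. The observed-data log-likelihood is recorded at
#' every iteration and is non-decreasing.
#'
#' Convergence: maximum absolute change in `(mu, Sigma)` at most `tol`
#' (default `1e-9`) or relative log-likelihood change at most `loglik_tol`
#' (default `1e-10`); at most `max_iter` (default 10000) iterations.
#'
#' @param data A data frame with `NA`s, or an [`fmi_patterns`] object.
#' @param control List overriding `tol`, `loglik_tol`, `max_iter`.
#' @return An object of class `saturated_fit`: `moments` (list `mu`, `sigma`,
#'   `source = "saturated_em"`), `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`.
#' @examples
#' d <- simulate_regression_population(100, seed = 2)
#' d$X[1:30] <- NA
#' fit_saturated_em(d)
#' @export
fit_saturated_em <- function(data, control = list()) {
  pats <- as_patterns(data)
  ctrl <- utils::modifyList(
    list(tol = 1e-9, loglik_tol = 1e-10, max_iter = 10000L), control)
  p <- pats$p
  N <- pats$N
  sat <- saturated_model(p, pats$var_names)

  start <- available_case_moments(pats)
  mu <- start$mu
  Sigma <- start$sigma

  trace <- numeric(0)
  converged <- FALSE
  failed <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    ll <- tryCatch(observed_loglik(sat, c(mu, vech(Sigma)), pats),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) {
      # degenerate update (e.g. too few cases for the dimension): report a
      # failed fit instead of raising, so replication loops can count it
      failed <- TRUE
      break
    }
    trace <- c(trace, ll)
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (pt in pats$patterns) {
      O <- pt$idx
      M <- setdiff(seq_len(p), O)
      n <- pt$n
      xb <- pt$xbar
      SOO <- pt$S + tcrossprod(xb)          # (1/n) sum x x' for observed block
      if (length(M) == 0L) {
        T1 <- T1 + n * xb
        T2 <- T2 + n * SOO
        next
      }
      SigOO <- Sigma[O, O, drop = FALSE]
      AOO <- tryCatch(chol2inv(chol(SigOO)), error = function(e) NULL)
      if (is.null(AOO)) {
        failed <- TRUE
        break
      }
      B <- Sigma[M, O, drop = FALSE] %*% AOO
      C <- Sigma[M, M, drop = FALSE] - B %*% Sigma[O, M, drop = FALSE]
      dO <- xb - mu[O]
      zbar <- mu[M] + as.vector(B %*% dO)           # mean of imputed block
      T1[O] <- T1[O] + n * xb
      T1[M] <- T1[M] + n * zbar
      # cross moments
      ExO_xO <- SOO
      ExO_z <- xb %*% t(mu[M]) + (pt$S + tcrossprod(xb) - xb %*% t(mu[O])) %*% t(B)
      Ezz <- tcrossprod(mu[M]) + mu[M] %*% t(dO) %*% t(B) +
        B %*% dO %*% t(mu[M]) +
        B %*% (pt$S + tcrossprod(dO)) %*% t(B) + C
      T2[O, O] <- T2[O, O] + n * ExO_xO
      T2[O, M] <- T2[O, M] + n * ExO_z
      T2[M, O] <- T2[M, O] + n * t(ExO_z)
      T2[M, M] <- T2[M, M] + n * Ezz
    }
    if (failed) break
    mu_new <- T1 / N
    Sigma_new <- symmetrize(T2 / N - tcrossprod(mu_new))
    delta <- max(abs(c(mu_new - mu, Sigma_new - Sigma)))
    rel_ll <- if (it > 1L)
      abs(ll - trace[it - 1L]) / (abs(trace[it - 1L]) + 1e-12) else Inf
    mu <- mu_new
    Sigma <- Sigma_new
    if (delta <= ctrl$tol || rel_ll <= ctrl$loglik_tol) {
      converged <- TRUE
      break
    }
    if (it >= ctrl$max_iter) break
  }
  ll_final <- tryCatch(observed_loglik(sat, c(mu, vech(Sigma)), pats),
                       error = function(e) NA_real_)
  if (converged && is.finite(ll_final)) {
    # Newton polish: EM converges linearly, so the stopping rule can leave
    # the moments a little short of the exact optimum; the analytic score
    # and information close the gap (the log-likelihood only increases)
    pol <- polish_fit(sat, c(mu, vech(Sigma)), ll_final, pats)
    mu <- pol$theta[seq_len(p)]
    Sigma <- unvech(pol$theta[-seq_len(p)], p)
    ll_final <- pol$loglik
  }
  if (is.finite(ll_final)) trace <- c(trace, ll_final)
  names(mu) <- pats$var_names
  dimnames(Sigma) <- list(pats$var_names, pats$var_names)
  structure(
    list(moments = list(mu = mu, sigma = Sigma, source = "saturated_em"),
         loglik = ll_final, loglik_trace = trace, n_iter = it,
         converged = converged, N = N),
    class = "saturated_fit"
  )
}

#' @export
print.saturated_fit <- function(x, ...) {
  cat("<saturated_fit> EM,", x$n_iter, "iteration(s), logLik =",
      format(x$loglik), "| converged:", x$converged, "\n")
  invisible(x)
}

#' @rdname fit_saturated_em
#' @param x A `saturated_fit` object.
#' @param ... Unused.
#' @export
glance.saturated_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_iter = x$n_iter, nobs = x$N,
                 converged = x$converged)
}
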