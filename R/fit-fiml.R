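# FIML estimation of structured models by quasi-Newton maximization of the
# observed-data log-likelihood. Variance-role parameters are log-transformed
# and correlation-role parameters atanh-transformed during optimization;
# everything reported (estimates, information, FMI) is on the natural scale.

par_transform <- function(model) {
  roles <- model$par_roles
  list(
    to = function(theta) {
      t <- theta
      v <- roles %in% c("variance", "error_var")
      t[v] <- log(pmax(theta[v], 1e-12))
      c <- roles == "factor_cov"
      t[c] <- atanh(pmin(pmax(theta[c], -0.999), 0.999))
      t
    },
    from = function(tpar) {
      t <- tpar
      v <- roles %in% c("variance", "error_var")
      t[v] <- exp(tpar[v])
      c <- roles == "factor_cov"
      t[c] <- tanh(tpar[c])
      t
    }
  )
}

# Map saturated (EM) moments to starting values for a structured model.
start_values <- function(model, moments) {
  mu <- as.numeric(moments$mu)
  S <- unname(as.matrix(moments$sigma))
  switch(model$kind,
    saturated = c(mu, vech(S)),
    regression = {
      beta <- S[1L, 2L] / S[1L, 1L]
      psi <- max(S[2L, 2L] - beta^2 * S[1L, 1L], 1e-4)
      c(mu[1L], max(S[1L, 1L], 1e-4), mu[2L] - beta * mu[1L], beta, psi)
    },
    cfa = {
      fmap <- model$factor_map
      vars <- model$var_names
      k <- length(fmap)
      lam <- numeric(model$p)
      names(lam) <- vars
      for (f in names(fmap)) {
        ii <- match(fmap[[f]], vars)
        blk <- S[ii, ii, drop = FALSE]
        off <- blk[lower.tri(blk)]
        avg <- if (length(off)) mean(off) else 0.25
        lam[ii] <- sqrt(max(avg, 0.04))
      }
      if (any(!is.finite(lam))) lam[] <- 0.5
      n_corr <- k * (k - 1L) / 2L
      phis <- numeric(0)
      if (n_corr > 0L) {
        pairs <- utils::combn(k, 2L)
        phis <- vapply(seq_len(ncol(pairs)), function(m) {
          i1 <- match(fmap[[pairs[1L, m]]], vars)
          i2 <- match(fmap[[pairs[2L, m]]], vars)
          cr <- mean(S[i1, i2]) / (mean(lam[i1]) * mean(lam[i2]))
          if (!is.finite(cr)) 0.3 else min(max(cr, -0.9), 0.9)
        }, numeric(1))
      }
      errv <- pmax(diag(S) - lam^2, 0.05)
      c(lam, phis, errv, mu)
    },
    abort_fmi("unknown model kind", "fmitools_model_error")
  )
}

# Damped Newton (Fisher-scoring) refinement. Steps use J = Delta' H1 Delta
# and the analytic score; backtracks when a step leaves the admissible region
# or lowers the log-likelihood. Stops when the step is negligible.
polish_fit <- function(model, theta, ll, pats, max_iter = 30L) {
  eval_ll <- function(th)
    tryCatch(observed_loglik(model, th, pats), error = function(e) NA_real_)
  grad <- function(th)
    tryCatch(model_score(model, th, pats), error = function(e) rep(NA_real_, model$q))
  g <- grad(theta)
  for (it in seq_len(max_iter)) {
    if (any(!is.finite(g))) break
    J <- tryCatch({
      mm <- model$moments_fn(theta)
      H1 <- h1_observed_info(mm, pats)
      if (model$kind == "saturated") H1
      else {
        D <- model_jacobian(model, theta)
        t(D) %*% H1 %*% D
      }
    }, error = function(e) NULL)
    if (is.null(J)) break
    step <- tryCatch(solve(J + diag(1e-10 * max(diag(J)), model$q), g),
                     error = function(e) NULL)
    if (is.null(step)) break
    accepted <- FALSE
    for (k in 0:25) {
      cand <- theta + step / 2^k
      ll_c <- eval_ll(cand)
      if (is.finite(ll_c) && ll_c >= ll - 1e-10 * max(1, abs(ll))) {
        theta <- cand
        ll <- ll_c
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
    g <- grad(theta)
    if (max(abs(step)) <= 1e-11 * max(1, max(abs(theta)))) break
  }
  gn <- if (any(!is.finite(g))) NA_real_ else max(abs(g))
  list(theta = theta, loglik = ll, grad_norm = gn)
}

#' Fit a structured model to incomplete data by FIML
#'
#' Maximizes the observed-data log-likelihood (see [observed_loglik()]) over
#' the free parameters with `stats::nlminb`, starting from saturated EM
#' moments mapped into the structured parameterization (overridable via
#' `start`). Non-convergence is reported through `converged = FALSE`, never
#' as an error, so simulation loops can account for failed replicates.
#'
#' @param data A data frame with `NA` for missing cells, or an
#'   [`fmi_patterns`] object.
#' @param model An [`fmi_model`].
#' @param start Optional starting vector of length `model$q`.
#' @param control List: `rel_tol` (relative log-likelihood tolerance, default
#'   `1e-9`), `grad_tol` (max-norm gradient tolerance relative to the
#'   log-likelihood scale, default `1e-5`), `iter_max`, `eval_max`.
#' @return An object of class `fiml_fit`: `model`, `theta` (named estimates),
#'   `loglik`, `converged`, `n_iter`, `grad_norm`, `N`, `patterns`.
#' @examples
#' d <- simulate_regression_population(200, seed = 1)
#' fit <- fit_fiml(d, regression_model())
#' tidy(fit)
#' @export
fit_fiml <- function(data, model, start = NULL, control = list()) {
  pats <- as_patterns(data)
  stopifnot(inherits(model, "fmi_model"))
  if (pats$p != model$p)
    abort_fmi("data and model disagree on the number of variables",
              "fmitools_dimension_error")
  ctrl <- utils::modifyList(
    list(rel_tol = 1e-9, grad_tol = 1e-5, iter_max = 1000L, eval_max = 4000L),
    control)
  if (!is.null(start) && length(start) != model$q)
    abort_fmi("start vector has the wrong length", "fmitools_config_error")

  if (is.null(start)) {
    em <- fit_saturated_em(pats)
    moms <- if (em$converged) em$moments else available_case_moments(pats)
    start <- start_values(model, moms)
    if (any(!is.finite(start)))
      start <- start_values(model, available_case_moments(pats))
  }
  tr <- par_transform(model)
  big <- 1e12
  neg_ll <- function(tpar) {
    th <- tr$from(tpar)
    v <- tryCatch(observed_loglik(model, th, pats), error = function(e) NA_real_)
    if (!is.finite(v)) big else -v
  }
  run_opt <- function(x0) tryCatch(
    stats::nlminb(x0, neg_ll,
                  control = list(rel.tol = min(ctrl$rel_tol, 1e-10),
                                 iter.max = ctrl$iter_max,
                                 eval.max = ctrl$eval_max)),
    error = function(e) NULL)
  opt <- run_opt(tr$to(start))

  if (is.null(opt) || !is.finite(opt$objective) || opt$objective >= big / 2) {
    theta <- start
    names(theta) <- model$par_names
    return(structure(list(model = model, theta = theta, loglik = NA_real_,
                          converged = FALSE, n_iter = 0L, grad_norm = NA_real_,
                          N = pats$N, patterns = pats), class = "fiml_fit"))
  }
  theta <- tr$from(opt$par)
  ll <- -opt$objective
  # Fisher-scoring polish with the analytic score and the first-dominant-term
  # information: quasi-Newton with finite-difference gradients leaves the
  # estimate a little off the stationary point, and the FMI identities for
  # saturated models hold only at an accurate optimum.
  polished <- polish_fit(model, theta, ll, pats)
  theta <- polished$theta
  ll <- polished$loglik
  grad_norm <- polished$grad_norm
  names(theta) <- model$par_names
  # nlminb's convergence code is unreliable with finite-difference gradients
  # ("false convergence" at tight tolerances); the stationarity of the
  # log-likelihood itself is the criterion, on a scale relative to |logLik|.
  converged <- is.finite(ll) && is.finite(grad_norm) &&
    grad_norm <= ctrl$grad_tol * max(1, abs(ll))
  structure(
    list(model = model, theta = theta, loglik = ll, converged = converged,
         n_iter = opt$iterations, grad_norm = grad_norm, N = pats$N,
         patterns = pats),
    class = "fiml_fit"
  )
}

#' @export
print.fiml_fit <- function(x, ...) {
  cat("<fiml_fit>", x$model$kind, "model, N =", x$N,
      "| logLik =", format(x$loglik), "| converged:", x$converged, "\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_fiml
#' @param x An `fiml_fit` object.
#' @param ... Unused.
#' @export
tidy.fiml_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta),
                 role = x$model$par_roles,
                 estimate = unname(x$theta))
}

#' @rdname fit_fiml
#' @export
glance.fiml_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, npar = x$model$q, nobs = x$N,
                 n_iter = x$n_iter, grad_norm = x$grad_norm,
                 converged = x$converged)
}
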