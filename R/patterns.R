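#' Partition incomplete data into missingness patterns
#'
#' Groups the rows of a rectangular numeric table by their missingness mask
#' (the set of observed variables) and computes per-pattern sufficient
#' statistics: case count `n`, observed-subvector mean `xbar`, and the
#' maximum-likelihood covariance `S` of the observed columns (divisor `n`,
#' matching the likelihood). Rows with no observed value contribute nothing to
#' the observed-data likelihood and are dropped with a warning.
#'
#' @param data A data frame or matrix with missing cells coded `NA`.
#' @return An object of class `fmi_patterns`: list with `patterns` (each a
#'   list `mask`, `idx`, `n`, `xbar`, `S`, `rows`), `N` (rows retained), `p`,
#'   `var_names`, and `n_dropped_empty`.
#' @examples
#' pattern_partition(data.frame(x = c(1, NA, 3), y = c(NA, 2, 4)))
#' @export
pattern_partition <- function(data) {
  x <- as.matrix(data)
  if (!is.numeric(x))
    abort_fmi("data must be numeric", "fmitools_data_error")
  if (nrow(x) < 1L || ncol(x) < 1L)
    abort_fmi("data must have at least one row and one column",
              "fmitools_empty_data")
  p <- ncol(x)
  vars <- colnames(x) %||% paste0("V", seq_len(p))
  obs <- !is.na(x)
  keep <- rowSums(obs) > 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    rlang::warn(sprintf("dropped %d all-missing row(s)", n_dropped))
    x <- x[keep, , drop = FALSE]
    obs <- obs[keep, , drop = FALSE]
  }
  if (nrow(x) == 0L)
    abort_fmi("no usable rows: every row is entirely missing",
              "fmitools_empty_data")
  row_ids <- which(keep)

  key <- as.vector(obs %*% 2^(seq_len(p) - 1L))
  groups <- split(seq_len(nrow(x)), key)
  patterns <- lapply(groups, function(rows) {
    idx <- which(obs[rows[1L], ])
    sub <- x[rows, idx, drop = FALSE]
    n_g <- length(rows)
    xbar <- colMeans(sub)
    cen <- sweep(sub, 2L, xbar)
    S <- crossprod(cen) / n_g
    list(mask = obs[rows[1L], ], idx = idx, n = n_g, xbar = xbar,
         S = S, rows = row_ids[rows])
  })
  names(patterns) <- NULL
  structure(
    list(patterns = patterns, N = nrow(x), p = p, var_names = vars,
         n_dropped_empty = n_dropped),
    class = "fmi_patterns"
  )
}

#' @export
print.fmi_patterns <- function(x, ...) {
  cat("<fmi_patterns>", length(x$patterns), "pattern(s),",
      x$N, "cases,", x$p, "variables")
  if (x$n_dropped_empty > 0L)
    cat(" (", x$n_dropped_empty, " all-missing rows dropped)", sep = "")
  cat("\n")
  for (pt in x$patterns) {
    cat(sprintf("  [%s] n = %d\n",
                paste(ifelse(pt$mask, "x", "."), collapse = ""), pt$n))
  }
  invisible(x)
}

as_patterns <- function(data) {
  if (inherits(data, "fmi_patterns")) data else pattern_partition(data)
}

# Single all-observed pattern carrying fixed pseudo-sample moments; used for
# the complete-data side of the information computations.
complete_pattern_set <- function(mu, sigma, N, var_names = NULL) {
  p <- length(mu)
  vars <- var_names %||% names(mu) %||% paste0("V", seq_len(p))
  structure(
    list(patterns = list(list(mask = rep(TRUE, p), idx = seq_len(p), n = N,
                              xbar = as.numeric(mu), S = unname(as.matrix(sigma)),
                              rows = integer())),
         N = N, p = p, var_names = vars, n_dropped_empty = 0L),
    class = "fmi_patterns"
  )
}
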