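# Internal linear-algebra and bookkeeping helpers.
#
# vech ordering convention (used everywhere in the package): lower triangle,
# column-major, diagonal included. For p = 3 the order is
# (1,1),(2,1),(3,1),(2,2),(3,2),(3,3).

vech <- function(m) m[lower.tri(m, diag = TRUE)]

# Inverse of vech: rebuild the full symmetric matrix.
unvech <- function(v, p) {
  m <- matrix(0, p, p)
  m[lower.tri(m, diag = TRUE)] <- v
  m <- m + t(m)
  diag(m) <- diag(m) / 2
  m
}

# Names for vech entries given variable names.
vech_names <- function(vars) {
  p <- length(vars)
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  paste0("cov_", vars[idx[, 1L]], ".", vars[idx[, 2L]])
}

# Map (i, j) -> position in vech(.) for a p x p symmetric matrix; returned as a
# full p x p matrix of positions so sub-pattern indices can be looked up.
vech_index_matrix <- function(p) {
  m <- matrix(0L, p, p)
  m[lower.tri(m, diag = TRUE)] <- seq_len(p * (p + 1L) / 2L)
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

# Duplication matrix D_p: vec(S) = D %*% vech(S) for symmetric S.
duplication_matrix <- function(p) {
  nv <- p * (p + 1L) / 2L
  D <- matrix(0, p * p, nv)
  vi <- vech_index_matrix(p)
  for (j in seq_len(p)) {
    for (i in seq_len(p)) {
      D[(j - 1L) * p + i, vi[i, j]] <- 1
    }
  }
  D
}

# Symmetrize (guards against floating-point drift).
symmetrize <- function(m) (m + t(m)) / 2

is_pos_def <- function(m, tol = 0) {
  ok <- TRUE
  tryCatch(chol(m), error = function(e) ok <<- FALSE)
  ok
}

# Disjoint substreams derived from one master seed, so the complete-data draw
# and the missingness draw of a dataset can be varied independently.
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + as.numeric(stream) * 1000003) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_fmi <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fmitools_error"))
}
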