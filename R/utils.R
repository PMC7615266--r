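`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_config <- function(...) {
  stop("configuration error: ", ..., call. = FALSE)
}

.assert_prob_vector <- function(p, what, n = 5L, tol = 1e-12) {
  if (!is.numeric(p) || length(p) != n || anyNA(p) || any(p < 0)) {
    .stop_config(what, " must be a non-negative numeric vector of length ", n)
  }
  if (abs(sum(p) - 1) > tol) {
    .stop_config(what, " must sum to 1 (got ", format(sum(p)), ")")
  }
  invisible(p)
}

# Stable short hash of an R object (polynomial rolling hash over its
# deparsed form, mod 2^31 - 1); used to stamp pipeline outputs.
.config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  v <- utf8ToInt(s)
  m <- 2147483647
  h <- 0
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    for (ch in chunk) h <- (h * 31 + ch) %% m
  }
  sprintf("%08x", as.integer(h))
}

# Minimum-norm least-squares solution via SVD.
.lsq_minnorm <- function(A, b, rtol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > max(sv$d[1], .Machine$double.eps) * rtol
  drop(sv$v[, keep, drop = FALSE] %*%
         ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep]))
}

# Moore-Penrose pseudo-inverse of a symmetric matrix.
.sym_pinv <- function(M, rtol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values[1]), .Machine$double.eps) * rtol
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

# Categorical sampling from per-row probability matrices.
# u: uniforms (length n); probs: n x K matrix of row-wise probabilities.
.sample_cat <- function(u, probs) {
  cp <- probs
  for (k in seq_len(ncol(probs))[-1]) cp[, k] <- cp[, k - 1] + probs[, k]
  idx <- rowSums(u > cp) + 1L
  pmin(idx, ncol(probs))
}

.rtruncnorm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}
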