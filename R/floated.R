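# Floated (group-specific) variances: attach a variance to every exposure
# category, reference included, such that the variance of any between-
# category log rate-ratio contrast is approximately the sum of the two
# categories' floated variances.

#' Compute floated variances for a categorical exposure
#'
#' Given the covariance matrix `V` of the `K - 1` estimated log rate ratios
#' (contrasts against the reference level), finds non-negative per-level
#' variances `f_0, ..., f_{K-1}` (reference included) minimising
#' `sum over pairs (i, j) of (f_i + f_j - C_ij)^2`, where `C_ij` is the
#' model variance of the log rate-ratio contrast between levels i and j
#' (`C_0j = V_jj` against the reference; `C_ij = V_ii + V_jj - 2 V_ij`
#' otherwise). When the unconstrained least-squares minimiser is
#' non-negative it is used directly — taking the minimum-norm solution when
#' the problem is under-determined, so for `K = 2` the single contrast
#' variance is split equally between the two levels; otherwise a
#' Lawson-Hanson non-negative least-squares solve is used. The achieved
#' maximum relative distortion of the contrast variances,
#' `max |f_i + f_j - C_ij| / C_ij`, is always reported so that cases where
#' floating misleads are visible.
#'
#' @param cov Either a covariance matrix of the non-reference log rate
#'   ratios, or a [fit_stratified_cox()] object (the exposure block of its
#'   covariance is used).
#' @param levels Optional level names, reference first; defaults to the
#'   fit's levels or `V`'s dimnames.
#' @param reference Reference level name used when `cov` is a bare matrix.
#' @return An object of class `floated_variances`: `levels`, `variances`
#'   (one per level, reference included) and `max_contrast_distortion`.
#' @examples
#' V <- matrix(c(4, 1, 1, 3), 2, 2)
#' float_variances(V, levels = c("ref", "a", "b"))
#' @export
float_variances <- function(cov, levels = NULL, reference = NULL) {
  if (inherits(cov, "stratcox")) {
    fit <- cov
    cov <- fit$cov[fit$exposure_cols, fit$exposure_cols, drop = FALSE]
    levels <- levels %||% fit$levels
  }
  V <- as.matrix(cov)
  K1 <- nrow(V)
  if (K1 < 1) stop("need at least two exposure levels", call. = FALSE)
  if (!isTRUE(all.equal(V, t(V), tolerance = 1e-8))) {
    stop("covariance matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  K <- K1 + 1L
  if (is.null(levels)) {
    nm <- rownames(V) %||% paste0("level", seq_len(K1))
    levels <- c(reference %||% "reference", nm)
  }
  stopifnot(length(levels) == K)

  # contrast variances C_ij over all unordered pairs, level 1 = reference
  pairs <- utils::combn(K, 2)
  Cij <- apply(pairs, 2, function(pr) {
    i <- pr[1] - 1L; j <- pr[2] - 1L      # 0-based: 0 = reference
    if (i == 0) V[j, j] else V[i, i] + V[j, j] - 2 * V[i, j]
  })
  A <- matrix(0, ncol(pairs), K)
  A[cbind(seq_len(ncol(pairs)), pairs[1, ])] <- 1
  A[cbind(seq_len(ncol(pairs)), pairs[2, ])] <- 1

  f <- .lsq_minnorm(A, Cij)
  if (any(f < -1e-10)) f <- .nnls(A, Cij)
  f <- pmax(f, 0)

  recon <- drop(A %*% f)
  ok <- Cij > 0
  distortion <- if (any(ok)) max(abs(recon[ok] - Cij[ok]) / Cij[ok]) else 0
  structure(list(levels = levels, variances = stats::setNames(f, levels),
                 max_contrast_distortion = distortion),
            class = "floated_variances")
}

#' @export
print.floated_variances <- function(x, digits = 4, ...) {
  cat("Floated variances (max contrast distortion",
      format(x$max_contrast_distortion, digits = 3), "):\n")
  print(round(x$variances, digits))
  invisible(x)
}

# Lawson-Hanson non-negative least squares.
.nnls <- function(A, b, tol = 1e-10) {
  p <- ncol(A)
  P <- rep(FALSE, p)
  f <- numeric(p)
  for (outer in seq_len(10 * p)) {
    w <- drop(crossprod(A, b - A %*% f))
    if (all(P) || max(w[!P]) <= tol) break
    P[which(!P)[which.max(w[!P])]] <- TRUE
    repeat {
      z <- numeric(p)
      z[P] <- .lsq_minnorm(A[, P, drop = FALSE], b)
      if (all(z[P] > tol)) {
        f <- z
        break
      }
      viol <- P & z <= tol
      alpha <- min(f[viol] / (f[viol] - z[viol]))
      f <- f + alpha * (z - f)
      P[P & f <= tol] <- FALSE
    }
  }
  f
}

#' Wald confidence interval on the floated scale
#'
#' `exp(beta +/- z * sqrt(variance))`; the reference level uses `beta = 0`
#' with its own floated variance, so it carries a genuine interval.
#'
#' @param beta_level Log rate ratio(s), 0 for the reference level.
#' @param variance_level Floated variance(s), non-negative.
#' @param z Normal quantile (default 1.96 for 95% coverage).
#' @return A two-column matrix (`lower`, `upper`) on the rate-ratio scale.
#' @export
floated_ci <- function(beta_level, variance_level, z = 1.96) {
  if (any(variance_level < 0, na.rm = TRUE)) {
    stop("floated variances must be non-negative", call. = FALSE)
  }
  half <- z * sqrt(variance_level)
  cbind(lower = exp(beta_level - half), upper = exp(beta_level + half))
}
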