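# Independent oracles, written naively and kept independent of the package
# internals they check.

# Hand-written Breslow partial log-likelihood for counting-process records:
# one term per event, risk set = records in the same stratum with
# t_start < t <= t_stop.
naive_cox_loglik <- function(beta, d, xcols) {
  X <- as.matrix(d[, xcols, drop = FALSE])
  ll <- 0
  for (i in which(d$event)) {
    t <- d$t_stop[i]
    risk <- d$stratum == d$stratum[i] & d$t_start < t & d$t_stop >= t
    ll <- ll + sum(X[i, ] * beta) -
      log(sum(exp(X[risk, , drop = FALSE] %*% beta)))
  }
  ll
}

# Brute-force maximiser of the naive partial likelihood.
naive_cox_mle <- function(d, xcols) {
  p <- length(xcols)
  if (p == 1) {
    opt <- stats::optimize(function(b) -naive_cox_loglik(b, d, xcols),
                           c(-8, 8), tol = 1e-12)
    return(opt$minimum)
  }
  opt <- stats::optim(rep(0, p),
                      function(b) -naive_cox_loglik(b, d, xcols),
                      method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 500))
  opt$par
}

# Iteratively refined grid search for the floated-variance objective
# sum over pairs (f_i + f_j - C_ij)^2, f >= 0.
grid_float_oracle <- function(C01, C02, C12, lo = 0, hi = 8) {
  obj <- function(f) {
    (f[1] + f[2] - C01)^2 + (f[1] + f[3] - C02)^2 + (f[2] + f[3] - C12)^2
  }
  center <- rep((lo + hi) / 2, 3)
  width <- (hi - lo) / 2
  step <- width / 10
  best <- center
  for (round in 1:6) {
    grid <- expand.grid(f0 = pmax(0, best[1] + seq(-width, width, step)),
                        f1 = pmax(0, best[2] + seq(-width, width, step)),
                        f2 = pmax(0, best[3] + seq(-width, width, step)))
    vals <- apply(grid, 1, obj)
    best <- as.numeric(grid[which.min(vals), ])
    width <- step * 2
    step <- width / 10
  }
  best
}

# Simpson quadrature of a piecewise-exponential survival curve on a fine
# monthly grid.
quadrature_le <- function(rates, breaks) {
  Sfun <- function(a) {
    out <- numeric(length(a))
    for (q in seq_along(a)) {
      H <- 0
      for (b in seq_along(rates)) {
        w <- max(0, min(a[q], breaks[b + 1]) - breaks[b])
        H <- H + w * rates[b]
      }
      out[q] <- exp(-H)
    }
    out
  }
  lo <- breaks[1]; hi <- breaks[length(breaks)]
  m <- 12 * (hi - lo)                     # monthly panels
  h <- (hi - lo) / (2 * m)
  xs <- seq(lo, hi, length.out = 2 * m + 1)
  ys <- Sfun(xs)
  h / 3 * (ys[1] + ys[2 * m + 1] +
           4 * sum(ys[seq(2, 2 * m, 2)]) + 2 * sum(ys[seq(3, 2 * m - 1, 2)]))
}
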