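# Sex- and age-band-stratified Cox partial likelihood with delayed entry
# (counting-process intervals (t_start, t_stop]), Breslow or Efron tie
# handling, Newton-Raphson maximisation with step-halving, covariance from
# the inverse observed information.
#
# Per stratum, risk-set sums over the ordered unique event times are
# accumulated with difference arrays: each record adds its contribution at
# the first event time it covers and removes it after the last, so one
# cumulative sum yields S0(t), S1(t), S2(t) for all event times at once.

.design_matrix <- function(records, exposure, reference, adjustment) {
  xv <- records[[exposure]]
  if (is.null(xv)) stop("exposure column ", exposure, " not found",
                        call. = FALSE)
  if (!is.factor(xv)) xv <- factor(xv)
  xv <- droplevels(xv)
  levs <- levels(xv)
  if (length(levs) < 2) {
    stop("exposure ", exposure,
         " is constant across records (non-identifiable)", call. = FALSE)
  }
  reference <- reference %||% levs[1]
  if (!reference %in% levs) {
    stop("reference level ", deparse(reference), " not among observed levels",
         call. = FALSE)
  }
  levs <- c(reference, setdiff(levs, reference))
  xv <- factor(xv, levels = levs)

  non_ref <- levs[-1]
  X <- matrix(0, nrow(records), length(non_ref),
              dimnames = list(NULL, paste0(exposure, "=", non_ref)))
  for (j in seq_along(non_ref)) X[, j] <- as.numeric(xv == non_ref[j])

  for (v in adjustment) {
    col <- records[[v]]
    if (is.null(col)) stop("adjustment column ", v, " not found",
                           call. = FALSE)
    if (is.numeric(col) || is.logical(col)) {
      X <- cbind(X, matrix(as.numeric(col), ncol = 1,
                           dimnames = list(NULL, v)))
    } else {
      f <- droplevels(if (is.factor(col)) col else factor(col))
      fl <- levels(f)
      if (length(fl) > 1) {
        D <- matrix(0, nrow(records), length(fl) - 1,
                    dimnames = list(NULL, paste0(v, "=", fl[-1])))
        for (j in seq_along(fl[-1])) D[, j] <- as.numeric(f == fl[j + 1])
        X <- cbind(X, D)
      }
    }
  }
  list(X = X, levels = levs, reference = reference,
       exposure_cols = seq_along(non_ref), exposure_values = xv)
}

# Precompute per-stratum risk-set bookkeeping (independent of beta).
.cox_prep <- function(start, stop, event, stratum) {
  strata <- split(seq_along(stop), stratum)
  out <- list()
  dropped <- 0L
  for (s in names(strata)) {
    idx <- strata[[s]]
    ev <- idx[event[idx]]
    if (!length(ev)) {
      dropped <- dropped + 1L
      next
    }
    ut <- sort(unique(stop[ev]))
    d <- as.integer(table(match(stop[ev], ut)))
    lo <- findInterval(start[idx], ut) + 1L       # first event time > start
    hi <- findInterval(stop[idx], ut)             # last event time <= stop
    # a degenerate event record (t_start == t_stop, boundary death) is at
    # risk at its own event time
    ev_local <- event[idx]
    k_ev <- rep(NA_integer_, length(idx))
    k_ev[ev_local] <- match(stop[idx][ev_local], ut)
    fix <- ev_local & !is.na(k_ev) & lo > k_ev
    lo[fix] <- k_ev[fix]
    at_risk <- lo <= hi
    out[[s]] <- list(idx = idx[at_risk], lo = lo[at_risk], hi = hi[at_risk],
                     ev_rows = idx[ev_local], k_ev = k_ev[ev_local],
                     ut = ut, d = d)
  }
  list(strata = out, n_dropped = dropped)
}

# Scatter rowsum() results into a zero matrix of nr rows.
.scatter <- function(nr, nc, values, group) {
  A <- matrix(0, nr, nc)
  rs <- rowsum(values, group)
  A[as.integer(rownames(rs)), ] <- rs
  A
}

# Log-likelihood, score and observed information at beta.
.cox_eval <- function(beta, X, prep, ties, want_info = TRUE) {
  p <- if (is.null(X)) 0L else ncol(X)
  eta <- if (p) drop(X %*% beta) else numeric(0)
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  if (p) {
    ii <- rep(seq_len(p), times = p:1)
    jj <- unlist(lapply(seq_len(p), function(a) a:p))
  }
  for (st in prep$strata) {
    d1 <- length(st$ut)
    r <- if (p) exp(eta[st$idx]) else rep(1, length(st$idx))
    grp_add <- st$lo
    grp_sub <- st$hi + 1L

    S0 <- cumsum(drop(.scatter(d1 + 1L, 1L, cbind(r), grp_add)) -
                 drop(.scatter(d1 + 1L, 1L, cbind(r), grp_sub)))[seq_len(d1)]
    if (p) {
      Xs <- X[st$idx, , drop = FALSE]
      Xr <- Xs * r
      A <- .scatter(d1 + 1L, p, Xr, grp_add) -
        .scatter(d1 + 1L, p, Xr, grp_sub)
      S1 <- apply(A, 2, cumsum)[seq_len(d1), , drop = FALSE]
      if (want_info) {
        X2r <- Xr[, ii, drop = FALSE] * Xs[, jj, drop = FALSE]
        A2 <- .scatter(d1 + 1L, length(ii), X2r, grp_add) -
          .scatter(d1 + 1L, length(ii), X2r, grp_sub)
        S2 <- apply(A2, 2, cumsum)[seq_len(d1), , drop = FALSE]
      }
      ev_eta_sum <- sum(eta[st$ev_rows])
      sum_x_ev <- colSums(X[st$ev_rows, , drop = FALSE])
    } else {
      ev_eta_sum <- 0
    }

    if (ties == "breslow") {
      ll <- ll + ev_eta_sum - sum(st$d * log(S0))
      if (p) {
        wk <- st$d / S0
        U <- U + sum_x_ev - colSums(S1 * wk)
        if (want_info) {
          M <- S1 / S0
          Iflat <- colSums(S2 * wk)
          Imat <- matrix(0, p, p)
          Imat[cbind(ii, jj)] <- Iflat
          Imat[cbind(jj, ii)] <- Iflat
          I <- I + Imat - crossprod(M, M * st$d)
        }
      }
    } else {  # efron
      re <- if (p) exp(eta[st$ev_rows]) else rep(1, length(st$ev_rows))
      S0e <- drop(rowsum(re, st$k_ev))
      ke <- sort(unique(st$k_ev))
      S0e_full <- numeric(d1); S0e_full[ke] <- S0e
      if (p) {
        Xe <- X[st$ev_rows, , drop = FALSE] * re
        S1e <- matrix(0, d1, p)
        rs1 <- rowsum(Xe, st$k_ev); S1e[as.integer(rownames(rs1)), ] <- rs1
        if (want_info) {
          X2e <- Xe[, ii, drop = FALSE] *
            X[st$ev_rows, jj, drop = FALSE]
          S2e <- matrix(0, d1, length(ii))
          rs2 <- rowsum(X2e, st$k_ev)
          S2e[as.integer(rownames(rs2)), ] <- rs2
        }
      }
      # expand (event time k, within-tie index j = 0..d_k - 1)
      kx <- rep(seq_len(d1), st$d)
      jx <- sequence(st$d) - 1
      frac <- jx / rep(st$d, st$d)
      S0j <- S0[kx] - frac * S0e_full[kx]
      ll <- ll + ev_eta_sum - sum(log(S0j))
      if (p) {
        S1j <- S1[kx, , drop = FALSE] - frac * S1e[kx, , drop = FALSE]
        U <- U + sum_x_ev - colSums(S1j / S0j)
        if (want_info) {
          S2j <- S2[kx, , drop = FALSE] - frac * S2e[kx, , drop = FALSE]
          Mj <- S1j / S0j
          Iflat <- colSums(S2j / S0j)
          Imat <- matrix(0, p, p)
          Imat[cbind(ii, jj)] <- Iflat
          Imat[cbind(jj, ii)] <- Iflat
          I <- I + Imat - crossprod(Mj)
        }
      }
    }
  }
  list(ll = ll, U = U, I = I)
}

.cox_newton <- function(X, prep, ties, eps = 1e-9, grad_tol = 1e-6,
                        max_iter = 50L, beta_cap = 15) {
  p <- ncol(X)
  beta <- numeric(p)
  cur <- .cox_eval(beta, X, prep, ties)
  if (p == 0L) {
    return(list(beta = beta, cov = matrix(0, 0, 0), loglik = cur$ll,
                score = numeric(0), iterations = 0L, converged = TRUE,
                separated = FALSE))
  }
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    step <- tryCatch(solve(cur$I, cur$U),
                     error = function(e) drop(.sym_pinv(cur$I) %*% cur$U))
    if (any(!is.finite(step))) step <- drop(.sym_pinv(cur$I) %*% cur$U)
    halved <- 0L
    # decreases below the round-off floor of the log-likelihood sum are
    # noise, not overshoot; accepting them lets the gradient criterion bite
    ll_slack <- (abs(cur$ll) + 1) * 1e-13
    repeat {
      cand <- beta + step
      new <- .cox_eval(cand, X, prep, ties)
      if (is.finite(new$ll) && new$ll >= cur$ll - ll_slack) break
      step <- step / 2
      halved <- halved + 1L
      if (halved > 25L) break
    }
    rel <- abs(new$ll - cur$ll) / (abs(cur$ll) + 0.1)
    beta <- cand
    cur <- new
    if (max(abs(cur$U)) < grad_tol && rel < eps) {
      converged <- TRUE
      break
    }
  }
  separated <- any(abs(beta) > beta_cap)
  if (separated) {
    warning("possible separation: coefficient capped at |beta| = ", beta_cap,
            call. = FALSE)
    beta <- pmin(pmax(beta, -beta_cap), beta_cap)
    cur <- .cox_eval(beta, X, prep, ties)
    converged <- FALSE
  }
  cov <- tryCatch(solve(cur$I), error = function(e) .sym_pinv(cur$I))
  cov <- (cov + t(cov)) / 2
  list(beta = beta, cov = cov, loglik = cur$ll, score = cur$U,
       iterations = iter, converged = converged, separated = separated)
}

#' Fit a stratified Cox proportional-hazards model
#'
#' Maximises the partial likelihood of a Cox model on the time-since-entry
#' timescale with delayed entry, stratified by the `stratum` column of the
#' Lexis-split records (sex x 5-year age-at-risk band), so proportional
#' hazards is assumed only within strata. The exposure enters as indicator
#' contrasts against a chosen reference level; additional adjustment
#' covariates enter as linear terms (numeric columns) or indicator
#' contrasts (categorical columns). Ties are handled by the Breslow
#' approximation by default (Efron available). Newton-Raphson with
#' step-halving; convergence requires relative log-likelihood change below
#' `1e-9` and score max-norm below `1e-6` within 50 iterations. The
#' covariance matrix is the inverse observed information.
#'
#' Rows with missing values in the exposure or adjustment columns are
#' dropped. Strata without events contribute nothing to the likelihood and
#' are dropped. Apparent separation (a coefficient drifting beyond +/-15 on
#' the log scale) is flagged with a warning and a capped estimate.
#'
#' @param records Survival records from [lexis_split()] /
#'   [prepare_cause()]: columns `t_start`, `t_stop`, `event`, `stratum`,
#'   plus the exposure and adjustment columns.
#' @param exposure Name of the categorical exposure column.
#' @param reference Reference level; defaults to the first observed level.
#' @param adjustment Character vector of additional covariate columns.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `stratcox`: `beta` (log rate ratios), `cov`,
#'   `loglik`, `loglik_null`, `n_events`, `n_records`, `iterations`,
#'   `converged`, plus exposure metadata. Methods: `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `confint`.
#' @seealso [rr_table()], [float_variances()]
#' @export
fit_stratified_cox <- function(records, exposure, reference = NULL,
                               adjustment = character(),
                               ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  need <- c("t_start", "t_stop", "event", "stratum")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)

  used <- c(exposure, adjustment)
  cc <- stats::complete.cases(records[, used, drop = FALSE])
  records <- records[cc, , drop = FALSE]
  if (!any(records$event)) stop("no events in the records", call. = FALSE)

  dm <- .design_matrix(records, exposure, reference, adjustment)
  prep <- .cox_prep(records$t_start, records$t_stop, records$event,
                    records$stratum)
  if (!length(prep$strata)) stop("no stratum contains an event",
                                 call. = FALSE)
  if (prep$n_dropped > 0) {
    message(prep$n_dropped, " stratum/strata without events dropped")
  }
  fit <- .cox_newton(dm$X, prep, ties)
  ll0 <- .cox_eval(numeric(ncol(dm$X)), dm$X, prep, ties,
                   want_info = FALSE)$ll

  events_by_level <- tapply(records$event, dm$exposure_values, sum)
  beta <- fit$beta
  names(beta) <- colnames(dm$X)
  dimnames(fit$cov) <- list(colnames(dm$X), colnames(dm$X))

  structure(list(beta = beta, cov = fit$cov, loglik = fit$loglik,
                 loglik_null = ll0, score = fit$score,
                 n_events = sum(records$event), n_records = nrow(records),
                 n_dropped_missing = sum(!cc),
                 n_strata_dropped = prep$n_dropped,
                 iterations = fit$iterations, converged = fit$converged,
                 separated = fit$separated,
                 exposure = exposure, reference = dm$reference,
                 levels = dm$levels, exposure_cols = dm$exposure_cols,
                 events_by_level = events_by_level,
                 adjustment = adjustment, ties = ties,
                 call = match.call()),
            class = "stratcox")
}

#' @export
print.stratcox <- function(x, digits = 4, ...) {
  cat("Stratified Cox model (", x$ties, " ties), exposure: ", x$exposure,
      " (reference: ", x$reference, ")\n", sep = "")
  cat(x$n_records, "records,", x$n_events, "events;",
      "log-likelihood", format(x$loglik, digits = digits + 3), "\n")
  if (!x$converged) cat("WARNING: not converged\n")
  se <- sqrt(pmax(diag(x$cov), 0))
  print(round(cbind(coef = x$beta, `exp(coef)` = exp(x$beta), se = se),
              digits))
  invisible(x)
}

#' @export
coef.stratcox <- function(object, ...) object$beta

#' @export
vcov.stratcox <- function(object, ...) object$cov

#' @export
logLik.stratcox <- function(object, ...) {
  structure(object$loglik, df = length(object$beta), class = "logLik")
}

#' @export
confint.stratcox <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(pmax(diag(object$cov), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta - z * se, object$beta + z * se)
  dimnames(ci) <- list(names(object$beta),
                       sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                  1 - (1 - level) / 2)))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.stratcox <- function(object, ...) {
  fl <- float_variances(object)
  tab <- rr_table(object, fl)
  structure(list(fit = object, floated = fl, rr = tab),
            class = "summary.stratcox")
}

#' @export
print.summary.stratcox <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nRate ratios with floated (group-specific) 95% CIs:\n")
  tab <- x$rr
  tab$RR <- round(tab$RR, digits)
  tab$lower <- round(tab$lower, digits)
  tab$upper <- round(tab$upper, digits)
  print(tab, row.names = FALSE)
  cat("max contrast-variance distortion:",
      format(x$floated$max_contrast_distortion, digits = 3), "\n")
  invisible(x)
}

#' Rate-ratio table with group-specific confidence intervals
#'
#' Tabulates the fitted rate ratio for every exposure level (reference
#' level RR = 1), a 95% confidence interval per level — group-specific
#' (floated) when floated variances are supplied, so the reference level
#' carries its own CI — and the number of deaths in each level.
#'
#' @param fit A [fit_stratified_cox()] result.
#' @param floated Optional [float_variances()] result; if omitted,
#'   conventional CIs are used and the reference CI is undefined.
#' @return A data frame with columns `level`, `RR`, `lower`, `upper`,
#'   `n_events`.
#' @export
rr_table <- function(fit, floated = NULL) {
  stopifnot(inherits(fit, "stratcox"))
  levs <- fit$levels
  beta <- c(0, fit$beta[fit$exposure_cols])
  if (is.null(floated)) {
    message("no floated variances supplied; conventional CIs, ",
            "reference CI undefined")
    se <- c(NA_real_, sqrt(pmax(diag(fit$cov)[fit$exposure_cols], 0)))
    lower <- exp(beta - 1.96 * se)
    upper <- exp(beta + 1.96 * se)
  } else {
    v <- floated$variances[match(levs, floated$levels)]
    ci <- floated_ci(beta, v)
    lower <- ci[, 1]
    upper <- ci[, 2]
  }
  data.frame(level = levs, RR = exp(beta), lower = lower, upper = upper,
             n_events = as.integer(fit$events_by_level[levs]),
             stringsAsFactors = FALSE)
}
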