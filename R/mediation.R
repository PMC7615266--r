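# Mediation by proportional attenuation: the change in the exposure's
# likelihood-ratio chi-square statistic (and in its log rate ratios) when
# candidate mediators are added to the model. This is an attenuation
# measure, not a counterfactual mediation estimand.

# Fit a design matrix (possibly empty) on prepared prep/bookkeeping.
.fit_design <- function(records, columns, ties = "breslow") {
  X <- matrix(0, nrow(records), 0)
  for (v in columns) {
    col <- records[[v]]
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
  prep <- .cox_prep(records$t_start, records$t_stop, records$event,
                    records$stratum)
  .cox_newton(X, prep, ties)
}

#' Likelihood-ratio chi-square for adding an exposure
#'
#' Fits two nested stratified Cox models on the identical record set — one
#' with the base covariates only, one additionally containing the exposure
#' contrasts — and returns the likelihood-ratio statistic
#' `chi2 = 2 (loglik_full - loglik_base)` with `df = K - 1` degrees of
#' freedom for a K-level exposure. Rows with missing values in any used
#' column are dropped from both fits so the likelihoods are comparable.
#'
#' @param records Survival records from [lexis_split()] /
#'   [prepare_cause()].
#' @param exposure Name of the categorical exposure column.
#' @param base_covariates Character vector of covariates in the base model
#'   (may be empty: the base is then the null model).
#' @param ties Tie handling, as in [fit_stratified_cox()].
#' @return A list: `chi2`, `df`, `loglik_base`, `loglik_full`,
#'   `converged`.
#' @export
lr_chi2 <- function(records, exposure, base_covariates = character(),
                    ties = "breslow") {
  used <- c(exposure, base_covariates)
  cc <- stats::complete.cases(records[, used, drop = FALSE])
  records <- records[cc, , drop = FALSE]
  if (!any(records$event)) stop("no events in the records", call. = FALSE)
  xv <- droplevels(factor(records[[exposure]]))
  if (nlevels(xv) < 2) stop("exposure is constant", call. = FALSE)

  f_base <- .fit_design(records, base_covariates, ties)
  f_full <- .fit_design(records, c(base_covariates, exposure), ties)
  if (!f_base$converged || !f_full$converged) {
    warning("nested fit did not converge; chi-square may be unreliable",
            call. = FALSE)
  }
  chi2 <- max(0, 2 * (f_full$loglik - f_base$loglik))
  list(chi2 = chi2, df = nlevels(xv) - 1L,
       loglik_base = f_base$loglik, loglik_full = f_full$loglik,
       converged = f_base$converged && f_full$converged)
}

#' Proportion of the association explained by mediators
#'
#' `100 * (1 - chi2_adjusted / chi2_unadjusted)`: the percent reduction in
#' the exposure's likelihood-ratio chi-square when mediators are added to
#' the model. Values outside `[0, 100]` are reported as computed
#' (suppression is possible and must remain visible).
#'
#' @param chi2_unadjusted LR statistic for the exposure in the
#'   confounder-only model; must be positive.
#' @param chi2_adjusted LR statistic for the exposure in the
#'   confounder-plus-mediator model.
#' @return Percent explained.
#' @export
proportion_explained <- function(chi2_unadjusted, chi2_adjusted) {
  if (!is.finite(chi2_unadjusted) || chi2_unadjusted <= 0) {
    stop("proportion explained is undefined when the unadjusted ",
         "chi-square is zero", call. = FALSE)
  }
  100 * (1 - chi2_adjusted / chi2_unadjusted)
}

#' Log rate-ratio attenuation for a stated contrast
#'
#' `100 * (1 - logRR_adjusted / logRR_unadjusted)` for the contrast between
#' two exposure levels (default: the headline contrast, lowest versus
#' highest education).
#'
#' @param fit_unadjusted,fit_adjusted [fit_stratified_cox()] objects
#'   sharing the exposure coding.
#' @param contrast Length-2 character vector `(level_a, level_b)`; the
#'   contrast is `log RR(level_a) - log RR(level_b)`.
#' @return Percent attenuation.
#' @export
logrr_attenuation <- function(fit_unadjusted, fit_adjusted,
                              contrast = c("none", "tertiary")) {
  stopifnot(inherits(fit_unadjusted, "stratcox"),
            inherits(fit_adjusted, "stratcox"))
  if (!identical(fit_unadjusted$levels, fit_adjusted$levels)) {
    stop("fits do not share the exposure coding", call. = FALSE)
  }
  get_lrr <- function(fit) {
    b <- c(0, fit$beta[fit$exposure_cols])
    names(b) <- fit$levels
    b[contrast[1]] - b[contrast[2]]
  }
  num <- get_lrr(fit_adjusted)
  den <- get_lrr(fit_unadjusted)
  if (!is.finite(den) || den == 0) {
    stop("attenuation undefined: unadjusted contrast log RR is zero",
         call. = FALSE)
  }
  unname(100 * (1 - num / den))
}

#' Mediation attenuation analysis
#'
#' Runs the full attenuation computation for one cause group: the
#' likelihood-ratio chi-square for the exposure with and without the
#' mediator set (both on the complete-case record set), the proportion of
#' the chi-square explained, the per-level log rate ratios before and after
#' adjustment, and the log-RR attenuation both for the stated headline
#' contrast and averaged across the non-reference levels.
#'
#' @inheritParams lr_chi2
#' @param mediators Character vector of mediator columns (categorical
#'   mediators as their category columns, continuous ones as numeric
#'   columns).
#' @param reference Exposure reference level.
#' @param contrast Headline contrast for the log-RR attenuation.
#' @return An object of class `mediation_result`.
#' @export
mediation_analysis <- function(records, exposure, mediators,
                               reference = "tertiary",
                               contrast = c("none", "tertiary"),
                               ties = "breslow") {
  used <- c(exposure, mediators)
  cc <- stats::complete.cases(records[, used, drop = FALSE])
  records <- records[cc, , drop = FALSE]

  un <- lr_chi2(records, exposure, character(), ties = ties)
  ad <- lr_chi2(records, exposure, mediators, ties = ties)

  fit_un <- fit_stratified_cox(records, exposure, reference = reference,
                               ties = ties)
  fit_ad <- fit_stratified_cox(records, exposure, reference = reference,
                               adjustment = mediators, ties = ties)

  lrr <- function(fit) {
    b <- c(0, fit$beta[fit$exposure_cols])
    names(b) <- fit$levels
    b
  }
  b_un <- lrr(fit_un)
  b_ad <- lrr(fit_ad)
  nonref <- setdiff(names(b_un), reference)
  mean_atten <- 100 * (1 - mean(b_ad[nonref]) / mean(b_un[nonref]))

  structure(list(chi2_unadjusted = un$chi2, chi2_adjusted = ad$chi2,
                 df = un$df,
                 prop_chi2_explained = proportion_explained(un$chi2,
                                                            ad$chi2),
                 logrr_unadjusted = b_un, logrr_adjusted = b_ad,
                 prop_logrr_explained = logrr_attenuation(fit_un, fit_ad,
                                                          contrast),
                 prop_logrr_explained_mean = mean_atten,
                 contrast = contrast, n_records = nrow(records),
                 n_events = fit_un$n_events),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  cat("Mediation attenuation (", x$n_events, " events)\n", sep = "")
  cat(sprintf("  LR chi2 (df = %d): unadjusted %.2f, adjusted %.2f\n",
              x$df, x$chi2_unadjusted, x$chi2_adjusted))
  cat(sprintf("  proportion of chi2 explained: %.1f%%\n",
              x$prop_chi2_explained))
  cat(sprintf("  log-RR attenuation (%s vs %s): %.1f%% (mean over levels: %.1f%%)\n",
              x$contrast[1], x$contrast[2], x$prop_logrr_explained,
              x$prop_logrr_explained_mean))
  invisible(x)
}
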