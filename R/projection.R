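# Projection: calibrate education-specific absolute death rates to a
# national life table given education prevalences and study rate ratios,
# then build survival trajectories and partial life-expectancy gaps.

#' Calibrate group-specific rates to a national rate
#'
#' Given a national annual death rate for an age band, group prevalences
#' `p` and rate ratios `r` (reference level = 1), solves for the anchor
#' rate `A = national_rate / sum(p * r)` and returns the per-group rates
#' `r * A`, so that the prevalence-weighted average of the group rates
#' reproduces the national rate exactly and the relative differences
#' between groups match the rate ratios. Prevalence vectors are used as
#' given (published prevalences rounded to whole percent are accepted when
#' their sum is within 0.02 of 1); the weighted-average identity holds by
#' construction regardless.
#'
#' @param national_rate National annual death rate(s), one per age band
#'   (deaths per person-year, non-negative).
#' @param prevalences Group prevalence vector `p`.
#' @param rr Rate-ratio vector `r`, strictly positive, reference = 1.
#' @return If `national_rate` is scalar, a vector of per-group rates;
#'   otherwise a matrix (bands x groups).
#' @examples
#' calibrate_rates(0.01, c(0.07, 0.16, 0.24, 0.27, 0.25),
#'                 c(1.62, 1.67, 1.62, 1.34, 1))
#' @export
calibrate_rates <- function(national_rate, prevalences, rr) {
  if (length(prevalences) != length(rr)) {
    stop("prevalences and rr must have the same length", call. = FALSE)
  }
  if (anyNA(prevalences) || any(prevalences < 0) ||
      abs(sum(prevalences) - 1) > 0.02) {
    stop("prevalences must be non-negative and sum to 1 (tolerance 0.02)",
         call. = FALSE)
  }
  if (anyNA(rr) || any(rr <= 0)) {
    stop("rate ratios must be strictly positive", call. = FALSE)
  }
  if (anyNA(national_rate) || any(national_rate < 0)) {
    stop("national rates must be non-negative", call. = FALSE)
  }
  A <- national_rate / sum(prevalences * rr)
  out <- outer(A, rr)
  colnames(out) <- names(rr)
  if (length(national_rate) == 1) drop(out) else out
}

#' Survival curve from piecewise-constant band rates
#'
#' `S(edge_m) = exp(-sum over earlier bands of width * rate)`, with
#' `S(start) = 1`; the hazard is constant within each band.
#'
#' @param rates Annual death rates, one per band.
#' @param breaks Band edges (length `length(rates) + 1`), contiguously
#'   covering the projection window.
#' @return Named vector of survival probabilities at the band edges.
#' @export
survival_curve <- function(rates, breaks = seq(35, by = 5,
                                               length.out = length(rates) + 1)) {
  if (length(breaks) != length(rates) + 1 ||
      is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing and bracket every band ",
         "(gap or overlap in band coverage)", call. = FALSE)
  }
  if (anyNA(rates) || any(rates < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  H <- cumsum(diff(breaks) * rates)
  stats::setNames(c(1, exp(-H)), breaks)
}

#' Partial (truncated) life expectancy from a survival curve
#'
#' Integrates the survival curve over the projection window assuming a
#' constant hazard within each band: the contribution of band `[a, a + w)`
#' with rate `lambda` is `S(a) * (1 - exp(-lambda * w)) / lambda`
#' (limit `w * S(a)` as `lambda -> 0`). Band rates are recovered from the
#' successive survival ratios, so the integral is exact for the
#' piecewise-exponential curve.
#'
#' @param S Survival probabilities at band edges, as returned by
#'   [survival_curve()] (names = edges, `S[1] = 1`).
#' @param breaks Band edges; defaults to the names of `S`.
#' @return Expected years lived within the window.
#' @examples
#' S <- survival_curve(rep(0.02, 7), seq(35, 70, 5))
#' partial_life_expectancy(S)  # (1 - exp(-0.7)) / 0.02
#' @export
partial_life_expectancy <- function(S, breaks = as.numeric(names(S))) {
  if (anyNA(breaks) || length(breaks) != length(S)) {
    stop("band edges must accompany the survival curve", call. = FALSE)
  }
  if (any(diff(S) > 1e-12) || S[1] != 1) {
    stop("S must be a non-increasing survival curve with S(start) = 1",
         call. = FALSE)
  }
  w <- diff(breaks)
  Sa <- S[-length(S)]
  Sb <- S[-1]
  ratio <- pmin(Sb / Sa, 1)
  lambda <- -log(ratio) / w
  contrib <- ifelse(lambda > 0, (Sa - Sb) / lambda, w * Sa)
  sum(contrib)
}

#' Project survival and life-expectancy gaps by education
#'
#' Combines a national life table (annual death rates by sex and 5-year
#' age band) with education prevalences and study rate ratios: each band's
#' national rate is calibrated into education-specific rates via
#' [calibrate_rates()], survival trajectories from `age_start` are built
#' per education level, and the partial life expectancy over
#' `[age_start, age_end)` and its gap versus the reference (tertiary)
#' level are computed.
#'
#' Rate ratios may differ by age range (as when distinct RRs apply at ages
#' 35-59 and 60-69): supply a list of RR vectors with names like
#' `"35-59"`, each applied to the bands whose lower edge falls in that
#' range, or a single vector applied to every band.
#'
#' @param life_table Data frame with columns `sex`, `age_lo`, `age_hi`,
#'   `annual_rate` (see [read_life_table()]).
#' @param prevalences List with per-sex education prevalence vectors
#'   (defaults to the study's education distribution: 7/16/24/27/25% of
#'   men and 13/21/29/25/12% of women from none to tertiary).
#' @param rr A named list per sex, each element either a length-5 RR
#'   vector or a list of age-range-specific RR vectors; or a single
#'   vector/list shared by both sexes.
#' @param age_start,age_end Projection window in years.
#' @param reference Reference education level for the gap.
#' @param extrapolation_age Optional age beyond `age_end`: when given, a
#'   second life-expectancy column continues each group's final band hazard
#'   at a constant rate up to this age (`le_extrapolated`,
#'   `gap_extrapolated`). This is an extension for sensitivity analysis,
#'   not part of the truncated headline estimate.
#' @return An object of class `eduproj` with data frames `rates`
#'   (sex, education, band, annual rate), `survival` (sex, education, age,
#'   S) and `life_expectancy` (sex, education, partial LE in years, gap
#'   versus reference). Methods: `print`, `plot`.
#' @export
project_education_survival <- function(life_table,
                                       prevalences = NULL,
                                       rr,
                                       age_start = 35, age_end = 70,
                                       reference = "tertiary",
                                       extrapolation_age = NULL) {
  if (is.null(prevalences)) {
    # study education distribution, renormalised from rounded percentages
    pm <- c(0.07, 0.16, 0.24, 0.27, 0.25)
    pf <- c(0.13, 0.21, 0.29, 0.25, 0.12)
    prevalences <- list(male = pm / sum(pm), female = pf / sum(pf))
  }
  if (!is.list(rr) || is.null(names(rr)) ||
      !all(SEX_LEVELS %in% names(rr))) {
    rr <- list(male = rr, female = rr)
  }
  rates_l <- list(); surv_l <- list(); le_l <- list()
  for (s in SEX_LEVELS) {
    lt <- life_table[life_table$sex == s, , drop = FALSE]
    lt <- lt[order(lt$age_lo), , drop = FALSE]
    lt <- lt[lt$age_lo >= age_start & lt$age_lo < age_end, , drop = FALSE]
    if (!nrow(lt) || lt$age_lo[1] > age_start ||
        lt$age_hi[nrow(lt)] < age_end ||
        any(lt$age_lo[-1] != lt$age_hi[-nrow(lt)])) {
      stop("life table does not contiguously cover [", age_start, ", ",
           age_end, ") for ", s, call. = FALSE)
    }
    breaks <- c(lt$age_lo, lt$age_hi[nrow(lt)])
    rr_band <- .rr_for_bands(rr[[s]], lt$age_lo)
    rates <- t(vapply(seq_len(nrow(lt)), function(b) {
      calibrate_rates(lt$annual_rate[b], prevalences[[s]], rr_band[[b]])
    }, numeric(5)))
    colnames(rates) <- EDU_LEVELS

    le <- numeric(5)
    le_ext <- numeric(5)
    for (k in seq_len(5)) {
      S <- survival_curve(rates[, k], breaks)
      surv_l[[length(surv_l) + 1L]] <- data.frame(
        sex = s, education = EDU_LEVELS[k], age = breaks, S = unname(S),
        stringsAsFactors = FALSE)
      le[k] <- partial_life_expectancy(S, breaks)
      if (!is.null(extrapolation_age)) {
        # continue the final band's hazard at a constant rate
        br2 <- c(breaks, extrapolation_age)
        S2 <- survival_curve(c(rates[, k], rates[nrow(rates), k]), br2)
        le_ext[k] <- partial_life_expectancy(S2, br2)
      }
    }
    rates_l[[s]] <- data.frame(
      sex = s, education = rep(EDU_LEVELS, each = nrow(lt)),
      age_lo = rep(lt$age_lo, 5), age_hi = rep(lt$age_hi, 5),
      annual_rate = as.vector(rates), stringsAsFactors = FALSE)
    le_l[[s]] <- data.frame(
      sex = s, education = EDU_LEVELS, partial_le = le,
      gap_vs_reference = le[match(reference, EDU_LEVELS)] - le,
      stringsAsFactors = FALSE)
    if (!is.null(extrapolation_age)) {
      le_l[[s]]$le_extrapolated <- le_ext
      le_l[[s]]$gap_extrapolated <-
        le_ext[match(reference, EDU_LEVELS)] - le_ext
    }
  }
  structure(list(rates = do.call(rbind, rates_l),
                 survival = do.call(rbind, surv_l),
                 life_expectancy = do.call(rbind, le_l),
                 window = c(age_start, age_end), reference = reference),
            class = "eduproj")
}

.rr_for_bands <- function(rr, band_lo) {
  if (!is.list(rr)) {
    stopifnot(length(rr) == 5)
    return(rep(list(rr), length(band_lo)))
  }
  ranges <- lapply(strsplit(names(rr), "-"), as.numeric)
  lapply(band_lo, function(a) {
    for (k in seq_along(ranges)) {
      if (a >= ranges[[k]][1] && a <= ranges[[k]][2]) return(rr[[k]])
    }
    stop("no rate-ratio vector covers age band starting at ", a,
         call. = FALSE)
  })
}

#' @export
print.eduproj <- function(x, digits = 2, ...) {
  cat("Education-specific survival projection over [", x$window[1], ", ",
      x$window[2], ")\n", sep = "")
  le <- x$life_expectancy
  le$partial_le <- round(le$partial_le, digits)
  le$gap_vs_reference <- round(le$gap_vs_reference, digits)
  print(le, row.names = FALSE)
  invisible(x)
}

#' @export
plot.eduproj <- function(x, sex = "male", ...) {
  sv <- x$survival[x$survival$sex == sex, , drop = FALSE]
  ages <- sort(unique(sv$age))
  M <- sapply(EDU_LEVELS, function(e) sv$S[sv$education == e])
  graphics::matplot(ages, M, type = "s", lty = 1, lwd = 2,
                    col = grDevices::hcl.colors(5, "Zissou 1"),
                    xlab = "Age (years)", ylab = "Survival probability",
                    main = paste("Projected survival by education,", sex),
                    ...)
  graphics::legend("bottomleft", legend = EDU_LEVELS, lty = 1, lwd = 2,
                   col = grDevices::hcl.colors(5, "Zissou 1"), bty = "n")
  invisible(x)
}

#' Parametric bootstrap for projected life-expectancy gaps
#'
#' Propagates the sampling uncertainty of the fitted log rate ratios into
#' the projection: draws are taken from the multivariate normal
#' distribution of the exposure coefficients (mean = estimates, covariance
#' = inverse observed information), each draw is pushed through
#' [project_education_survival()], and quantiles of the none-versus-
#' reference life-expectancy gap are returned. This is an uncertainty
#' extension; the headline projection itself is deterministic.
#'
#' @param fit A [fit_stratified_cox()] object for the education exposure.
#' @param life_table National life table (see [read_life_table()]).
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed.
#' @param probs Quantiles to report.
#' @param ... Passed to [project_education_survival()].
#' @return A data frame per sex with the gap quantiles (years).
#' @export
project_gap_bootstrap <- function(fit, life_table, n_boot = 200, seed = 1,
                                  probs = c(0.025, 0.5, 0.975), ...) {
  stopifnot(inherits(fit, "stratcox"))
  idx <- fit$exposure_cols
  beta <- fit$beta[idx]
  V <- fit$cov[idx, idx, drop = FALSE]
  L <- chol((V + t(V)) / 2)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_boot * length(beta)), n_boot)
  draws <- sweep(Z %*% L, 2, beta, `+`)
  gaps <- matrix(NA_real_, n_boot, 2,
                 dimnames = list(NULL, SEX_LEVELS))
  for (b in seq_len(n_boot)) {
    rr <- stats::setNames(exp(c(0, draws[b, ]))[match(EDU_LEVELS,
                                                      fit$levels)],
                          EDU_LEVELS)
    le <- project_education_survival(life_table, rr = rr, ...)$life_expectancy
    for (s in SEX_LEVELS) {
      gaps[b, s] <- le$gap_vs_reference[le$sex == s &
                                          le$education == "none"]
    }
  }
  out <- data.frame(sex = SEX_LEVELS,
                    t(apply(gaps, 2, stats::quantile, probs = probs)),
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
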