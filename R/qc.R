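# Cohort quality control: sequential exclusion rules and derivation of the
# analysis categories.

.REQUIRED_COVARIATES <- c("smoking", "alcohol", "activity", "height",
                          "weight", "waist", "hip", "sbp", "dbp")

#' Apply the sequential exclusion rules
#'
#' Excludes, in fixed order, participants (1) aged `age_cap` or older at
#' recruitment, (2) with missing education, (3) with missing or extreme
#' covariate data, and (4) with an uncertain cause of death. Each row is
#' excluded at most once, by the first rule it violates, so the ledger
#' counts are sequential ("a further n ...").
#'
#' Extreme covariate thresholds: height < 120 or > 200 cm; weight < 35 or
#' > 250 kg; BMI < 15 or > 60 kg/m2; waist < 60 or > 180 cm; hip < 70 or
#' > 180 cm; waist-to-hip ratio < 0.5 or > 1.5.
#'
#' @param cohort A cohort data frame (see [generate_cohort()] for the
#'   schema).
#' @param age_cap Entry-age exclusion threshold in years.
#' @return A list with `cohort` (the retained rows) and `ledger`, a data
#'   frame of class `exclusion_ledger` with one row per rule
#'   (`rule`, `n_excluded`, `n_remaining`) and attributes `total_in`,
#'   `total_out`.
#' @export
apply_exclusions <- function(cohort, age_cap = 85) {
  need <- c("entry_age", "education", .REQUIRED_COVARIATES, "cause_uncertain")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n0 <- nrow(cohort)

  r1 <- is.na(cohort$entry_age) | cohort$entry_age >= age_cap
  r2 <- !r1 & is.na(cohort$education)

  cov_missing <- Reduce(`|`, lapply(.REQUIRED_COVARIATES,
                                    function(v) is.na(cohort[[v]])))
  bmi <- cohort$weight / (cohort$height / 100)^2
  whr <- cohort$waist / cohort$hip
  extreme <- (cohort$height < 120 | cohort$height > 200 |
              cohort$weight < 35 | cohort$weight > 250 |
              bmi < 15 | bmi > 60 |
              cohort$waist < 60 | cohort$waist > 180 |
              cohort$hip < 70 | cohort$hip > 180 |
              whr < 0.5 | whr > 1.5)
  extreme[is.na(extreme)] <- FALSE
  r3 <- !r1 & !r2 & (cov_missing | extreme)

  r4 <- !r1 & !r2 & !r3 & !is.na(cohort$cause_uncertain) &
    cohort$cause_uncertain

  excl <- cbind(r1, r2, r3, r4)
  n_excl <- colSums(excl)
  n_remaining <- n0 - cumsum(n_excl)
  ledger <- data.frame(
    rule = c("age_ge_cap", "missing_education",
             "missing_or_extreme_covariate", "uncertain_cause"),
    n_excluded = as.integer(n_excl),
    n_remaining = as.integer(n_remaining),
    stringsAsFactors = FALSE)
  attr(ledger, "total_in") <- n0
  attr(ledger, "total_out") <- as.integer(n_remaining[4])
  class(ledger) <- c("exclusion_ledger", "data.frame")

  list(cohort = cohort[!rowSums(excl), , drop = FALSE], ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Exclusion ledger:", attr(x, "total_in"), "in,",
      attr(x, "total_out"), "retained\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Derive the analysis categories
#'
#' Adds to an exclusion-filtered cohort the derived quantities and
#' categorical variables used in the analyses: BMI and waist-to-hip ratio;
#' education, smoking, alcohol and physical-activity factors; income in
#' five bands (no income reported, <1500, 1500 to <3000, 3000 to <4500,
#' >=4500 pesos/month; band lower bounds closed); quintiles of the area
#' deprivation score (boundary values assigned to the lower quintile); and
#' five-level diabetes status (no diabetes; undiagnosed, i.e. no previous
#' diagnosis with HbA1c strictly above 6.5 percent; previously diagnosed
#' with HbA1c <9, 9 to <11, or >=11 percent). Undiagnosed participants with
#' missing HbA1c are retained with diabetes status `"unknown"`.
#'
#' @param cohort A cohort data frame, exclusions already applied.
#' @param sdi_reference Optional numeric vector from which the deprivation
#'   score quintile cut-points are computed; defaults to the cohort's own
#'   `sdi` column.
#' @return The cohort with added columns `bmi`, `whr`, `education_cat`,
#'   `income_cat`, `sdi_quintile`, `smoking_cat`, `alcohol_cat`,
#'   `activity_cat`, `diabetes_cat`.
#' @export
derive_categories <- function(cohort, sdi_reference = NULL) {
  cohort$bmi <- cohort$weight / (cohort$height / 100)^2
  cohort$whr <- cohort$waist / cohort$hip
  cohort$education_cat <- factor(cohort$education, levels = EDU_LEVELS)
  cohort$smoking_cat <- factor(cohort$smoking, levels = SMOKING_LEVELS)
  cohort$alcohol_cat <- factor(cohort$alcohol, levels = ALCOHOL_LEVELS)
  cohort$activity_cat <- factor(cohort$activity, levels = ACTIVITY_LEVELS)

  inc <- cohort$income_monthly
  income_cat <- rep(NA_character_, nrow(cohort))
  income_cat[!is.na(inc) & inc == 0] <- "no_income"
  income_cat[!is.na(inc) & inc > 0 & inc < 1500] <- "lt_1500"
  income_cat[!is.na(inc) & inc >= 1500 & inc < 3000] <- "1500_to_lt3000"
  income_cat[!is.na(inc) & inc >= 3000 & inc < 4500] <- "3000_to_lt4500"
  income_cat[!is.na(inc) & inc >= 4500] <- "ge_4500"
  cohort$income_cat <- factor(income_cat, levels = INCOME_LEVELS)

  ref <- sdi_reference %||% cohort$sdi
  if (all(is.na(ref))) {
    cohort$sdi_quintile <- rep(NA_integer_, nrow(cohort))
  } else {
    # linear-interpolation percentiles; boundary values fall in the lower
    # quintile via right-closed intervals
    cuts <- stats::quantile(ref, probs = c(0.2, 0.4, 0.6, 0.8),
                            na.rm = TRUE, type = 7, names = FALSE)
    cohort$sdi_quintile <- as.integer(cut(cohort$sdi,
                                          breaks = c(-Inf, cuts, Inf),
                                          labels = FALSE, right = TRUE))
  }

  dc <- .diabetes_category(cohort$diabetes_diagnosed, cohort$hba1c)
  dc[is.na(dc) & !is.na(cohort$diabetes_diagnosed) &
       !cohort$diabetes_diagnosed] <- "unknown"
  cohort$diabetes_cat <- factor(dc, levels = c(DIABETES_LEVELS, "unknown"))
  cohort
}
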