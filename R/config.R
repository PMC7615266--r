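#' Cause-specific piecewise-constant hazard model
#'
#' Defines the mortality model used by the synthetic-cohort generator:
#' per-cause baseline annual death rates, piecewise constant on 5-year
#' age bands and specific to sex, multiplied on the hazard scale by a
#' direct education effect and by log-linear mediator effects.
#'
#' The default baseline total hazard doubles every decade of age
#' (starting from 0.0015/yr for men and 0.0010/yr for women at age 35-39)
#' and is split across the eight cause groups in fixed proportions that
#' mirror the cause-of-death mix of premature adult mortality in urban
#' Mexico (vascular and renal/acute-diabetic deaths dominant, cancer
#' comparatively rare).
#'
#' @param age_breaks Increasing numeric vector of band edges (years); bands
#'   are half-open `[a, a+5)`. Event times beyond the last break are never
#'   generated (such participants are administratively censored).
#' @param causes Character vector of disjoint cause tokens.
#' @param baseline `NULL` for the default, or a list with elements `male`
#'   and `female`, each a `length(causes) x (length(age_breaks)-1)` matrix
#'   of non-negative annual rates (rows = causes, columns = age bands).
#' @param education_logrr Direct (unmediated) log rate ratio per education
#'   level, ordered as [education_levels()]; either a length-5 vector shared
#'   by all causes or a `length(causes) x 5` matrix. The reference
#'   (tertiary) entry is conventionally 0.
#' @param mediator_coef `NULL` for no mediator effects on the hazard, or a
#'   list as returned by [default_mediator_coef()]: log-hazard slopes for
#'   centred continuous mediators and log-hazard contrasts for categorical
#'   mediator levels.
#' @return An object of class `hazard_model`.
#' @export
hazard_model <- function(age_breaks = seq(35, 105, by = 5),
                         causes = CAUSE_BASE,
                         baseline = NULL,
                         education_logrr = log(c(1.35, 1.30, 1.22, 1.12, 1)),
                         mediator_coef = default_mediator_coef()) {
  if (length(age_breaks) < 2 || is.unsorted(age_breaks, strictly = TRUE)) {
    .stop_config("age_breaks must be strictly increasing")
  }
  nb <- length(age_breaks) - 1L
  if (is.null(baseline)) {
    baseline <- .default_baseline(age_breaks, causes)
  }
  for (s in SEX_LEVELS) {
    m <- baseline[[s]]
    if (!is.matrix(m) || nrow(m) != length(causes) || ncol(m) != nb) {
      .stop_config("baseline$", s, " must be a ", length(causes), " x ", nb,
                   " matrix")
    }
    if (anyNA(m) || any(m < 0)) {
      .stop_config("negative or missing baseline hazard rate")
    }
    rownames(baseline[[s]]) <- causes
  }
  if (is.matrix(education_logrr)) {
    if (nrow(education_logrr) != length(causes) || ncol(education_logrr) != 5) {
      .stop_config("education_logrr matrix must be length(causes) x 5")
    }
  } else if (length(education_logrr) != 5) {
    .stop_config("education_logrr must have one entry per education level")
  }
  if (anyNA(education_logrr) || any(!is.finite(education_logrr))) {
    .stop_config("education_logrr must be finite")
  }
  structure(list(age_breaks = age_breaks, causes = causes,
                 baseline = baseline, education_logrr = education_logrr,
                 mediator_coef = mediator_coef),
            class = "hazard_model")
}

.default_baseline <- function(age_breaks, causes) {
  mid <- (age_breaks[-length(age_breaks)] + age_breaks[-1]) / 2
  # cause mix follows the premature-death distribution: cardiac 19%,
  # stroke 6%, hepatobiliary 8.5%, renal/acute diabetic 20%, cancer 16.5%,
  # respiratory 13%, infectious 6.5%, other 10.5%
  mix <- c(cardiac = 0.190, stroke = 0.060, hepatobiliary = 0.085,
           renal_and_acute_diabetic = 0.200, cancer = 0.165,
           respiratory = 0.130, infectious = 0.065, other = 0.105)
  w <- if (all(causes %in% names(mix))) {
    unname(mix[causes] / sum(mix[causes]))
  } else {
    rep(1 / length(causes), length(causes))
  }
  r0 <- c(male = 0.0015, female = 0.0010)
  out <- lapply(SEX_LEVELS, function(s) {
    tot <- r0[[s]] * 2^((mid - 35) / 10)
    m <- outer(w, tot)
    rownames(m) <- causes
    m
  })
  names(out) <- SEX_LEVELS
  out
}

#' @rdname hazard_model
#' @details `default_mediator_coef()` returns the default log-hazard effects
#'   of the mediators: per-unit slopes for centred systolic blood pressure,
#'   weight, waist and hip, and level contrasts (versus the first level) for
#'   smoking, alcohol, physical activity and diabetes status.
#' @export
default_mediator_coef <- function() {
  list(
    continuous = c(sbp = 0.012, weight = 0.004, waist = 0.006, hip = -0.004),
    centers    = c(sbp = 125,   weight = 72,    waist = 95,    hip = 103),
    smoking  = c(former = 0.10, occasional = 0.15,
                 current_lt10 = 0.30, current_ge10 = 0.55),
    alcohol  = c(former = 0.25, lt_weekly = 0.00,
                 upto_2_per_week = 0.05, gt_2_per_week = 0.20),
    activity = c(upto_twice_weekly = -0.12, ge_three_weekly = -0.22),
    diabetes = c(undiagnosed = 0.65, diagnosed_hba1c_lt9 = 0.80,
                 diagnosed_hba1c_9_11 = 1.10, diagnosed_hba1c_ge11 = 1.40)
  )
}

#' Default education-conditional mediator distributions
#'
#' Per-sex, per-education-level parameters for the baseline covariates
#' generated by [generate_cohort()]. Continuous mediators are Gaussian with
#' education-specific means (systolic blood pressure, BMI, waist and HbA1c
#' decline with increasing education; the gradients follow the baseline
#' cross-tabulations of the source cohort qualitatively); categorical
#' mediators are multinomial with education-specific probabilities.
#' Mediators are drawn conditionally independently given education and sex.
#'
#' Matrix parameters have one row per sex (male, female) and one column per
#' education level in the order of [education_levels()].
#'
#' @return A list of per-mediator parameter blocks.
#' @export
default_mediator_model <- function() {
  m2 <- function(male, female) {
    m <- rbind(male = male, female = female)
    colnames(m) <- EDU_LEVELS
    m
  }
  # 3-way smoking/drinking tabulations expanded to the 5-level analysis
  # categories by fixed within-current splits.
  smoke5 <- function(current, former, split) {
    never <- 1 - current - former
    p <- cbind(never, former,
               current * split[1], current * split[2], current * split[3])
    colnames(p) <- SMOKING_LEVELS
    rownames(p) <- EDU_LEVELS
    p
  }
  alc5 <- function(current, former, split) {
    never <- 1 - current - former
    p <- cbind(never, former,
               current * split[1], current * split[2], current * split[3])
    colnames(p) <- ALCOHOL_LEVELS
    rownames(p) <- EDU_LEVELS
    p
  }
  act3 <- function(none, upto2) {
    p <- cbind(none, upto2, 1 - none - upto2)
    colnames(p) <- ACTIVITY_LEVELS
    rownames(p) <- EDU_LEVELS
    p
  }
  list(
    height = list(mean = c(male = 165, female = 152),
                  sd = c(male = 7, female = 6), range = c(126, 194)),
    bmi = list(mean = m2(c(27.7, 28.2, 28.2, 28.1, 27.8),
                         c(30.2, 30.4, 30.0, 29.1, 28.0)),
               sd = c(male = 4.2, female = 5.1), range = c(16, 55)),
    waist = list(mean = m2(c(97, 97, 96, 96, 96),
                           c(97, 96, 94, 91, 89)),
                 sd = c(male = 10, female = 12), range = c(62, 175)),
    whr = list(mean = c(male = 0.950, female = 0.875),
               sd = c(male = 0.045, female = 0.050), range = c(0.62, 1.35)),
    sbp = list(mean = m2(c(133, 132, 129, 126, 126),
                         c(134, 130, 126, 122, 120)),
               sd = c(male = 16, female = 17), range = c(86, 224)),
    dbp = list(mean = m2(c(85, 85, 85, 84, 84),
                         c(85, 84, 83, 81, 80)),
               sd = c(male = 10, female = 10), range = c(46, 138)),
    hba1c = list(mean = m2(c(5.8, 5.8, 5.7, 5.6, 5.5),
                           c(5.9, 5.8, 5.7, 5.5, 5.4)),
                 sd = c(male = 1.0, female = 0.9), range = c(3.9, 14),
                 diagnosed_mean = 8.6, diagnosed_sd = 1.9,
                 diagnosed_range = c(4.8, 16)),
    diabetes_diagnosed = list(prob = m2(c(0.19, 0.19, 0.16, 0.10, 0.08),
                                        c(0.23, 0.19, 0.13, 0.07, 0.04))),
    smoking = list(prob = list(
      male = smoke5(current = c(0.44, 0.48, 0.52, 0.57, 0.47),
                    former = c(0.35, 0.35, 0.29, 0.25, 0.27),
                    split = c(0.35, 0.40, 0.25)),
      female = smoke5(current = c(0.12, 0.17, 0.24, 0.32, 0.32),
                      former = c(0.13, 0.13, 0.14, 0.15, 0.19),
                      split = c(0.50, 0.35, 0.15)))),
    alcohol = list(prob = list(
      male = alc5(current = c(0.64, 0.71, 0.76, 0.80, 0.84),
                  former = c(0.27, 0.23, 0.18, 0.15, 0.09),
                  split = c(0.45, 0.40, 0.15)),
      female = alc5(current = c(0.48, 0.58, 0.64, 0.69, 0.73),
                    former = c(0.16, 0.14, 0.11, 0.09, 0.07),
                    split = c(0.45, 0.40, 0.15)))),
    activity = list(prob = list(
      male = act3(none = c(0.85, 0.80, 0.73, 0.67, 0.58),
                  upto2 = c(0.05, 0.08, 0.12, 0.17, 0.17)),
      female = act3(none = c(0.90, 0.87, 0.83, 0.77, 0.68),
                    upto2 = c(0.04, 0.04, 0.05, 0.06, 0.08)))),
    income = list(p_none = m2(c(0.08, 0.06, 0.05, 0.04, 0.02),
                              c(0.75, 0.72, 0.68, 0.60, 0.40)),
                  mean = m2(c(1400, 1800, 2400, 3200, 6700),
                            c(1100, 1300, 1600, 2500, 5200)),
                  sdlog = 0.9),
    sdi = list(mean = m2(c(0.72, 0.73, 0.74, 0.76, 0.81),
                         c(0.72, 0.73, 0.75, 0.77, 0.82)),
               sd = 0.10, range = c(0.02, 0.995))
  )
}

#' Synthetic cohort configuration
#'
#' Bundles all parameters of the synthetic-cohort generator: cohort size and
#' composition, education distribution by sex, entry-age distribution,
#' recruitment window, administrative censoring date, the
#' education-conditional mediator model and the cause-specific hazard model.
#'
#' Education probability vectors are validated and renormalised (published
#' prevalences are often rounded to whole percent, so sums within 0.05 of 1
#' are accepted and rescaled to sum exactly to 1).
#'
#' @param n_participants Number of participants to generate.
#' @param fraction_male Proportion of men, in `[0, 1]`.
#' @param education_probs_by_sex List with elements `male` and `female`,
#'   each a length-5 probability vector over [education_levels()].
#' @param entry_age List with `mean`, `sd`, `min`, `max`: entry ages are
#'   truncated-normal on `[min, max)`.
#' @param recruitment_window Length-2 `Date` vector; entry dates are uniform
#'   over this interval.
#' @param admin_censor_date Administrative censoring date (`Date`).
#' @param mediator_model Per-mediator distribution parameters, defaulting to
#'   [default_mediator_model()].
#' @param hazard_model A [hazard_model()] object.
#' @param seed Integer root seed; all generator randomness derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20000,
                          fraction_male = 0.33,
                          education_probs_by_sex = NULL,
                          entry_age = list(mean = 50.7, sd = 10.8,
                                           min = 35, max = 85),
                          recruitment_window = as.Date(c("1998-01-01",
                                                         "2004-12-31")),
                          admin_censor_date = as.Date("2020-12-31"),
                          mediator_model = NULL,
                          hazard_model = NULL,
                          seed = 1L) {
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      is.na(n_participants) || n_participants < 1 ||
      n_participants != floor(n_participants)) {
    .stop_config("n_participants must be a positive integer")
  }
  if (!is.numeric(fraction_male) || fraction_male < 0 || fraction_male > 1) {
    .stop_config("fraction_male must lie in [0, 1]")
  }
  if (is.null(education_probs_by_sex)) {
    education_probs_by_sex <- list(
      male = c(0.07, 0.16, 0.24, 0.27, 0.25),
      female = c(0.13, 0.21, 0.29, 0.25, 0.12))
  }
  for (s in SEX_LEVELS) {
    p <- education_probs_by_sex[[s]]
    if (!is.numeric(p) || length(p) != 5 || anyNA(p) || any(p < 0)) {
      .stop_config("education_probs_by_sex$", s,
                   " must be 5 non-negative probabilities")
    }
    if (abs(sum(p) - 1) > 0.05) {
      .stop_config("education_probs_by_sex$", s, " sums to ",
                   format(sum(p)), ", not 1")
    }
    education_probs_by_sex[[s]] <- p / sum(p)
  }
  if (!all(c("mean", "sd", "min", "max") %in% names(entry_age)) ||
      entry_age$min < 35 || entry_age$max > 85 ||
      entry_age$min >= entry_age$max) {
    .stop_config("entry_age must give mean, sd and a range within [35, 85)")
  }
  recruitment_window <- as.Date(recruitment_window)
  admin_censor_date <- as.Date(admin_censor_date)
  if (length(recruitment_window) != 2 ||
      recruitment_window[1] > recruitment_window[2]) {
    .stop_config("recruitment_window must be an ordered pair of dates")
  }
  if (is.null(mediator_model)) mediator_model <- default_mediator_model()
  if (is.null(hazard_model)) hazard_model <- edumort::hazard_model()
  if (!inherits(hazard_model, "hazard_model")) {
    .stop_config("hazard_model must be built with hazard_model()")
  }
  structure(list(n_participants = as.integer(n_participants),
                 fraction_male = fraction_male,
                 education_probs_by_sex = education_probs_by_sex,
                 entry_age = entry_age,
                 recruitment_window = recruitment_window,
                 admin_censor_date = admin_censor_date,
                 mediator_model = mediator_model,
                 hazard_model = hazard_model,
                 seed = as.integer(seed)),
            class = "cohort_config")
}
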