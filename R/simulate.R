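# Synthetic cohort generation: education-graded mediators, piecewise-
# exponential competing-cause event times, administrative censoring.
#
# Reproducibility contract: all randomness flows from config$seed. Draws are
# made in fixed vectorised blocks keyed by participant index (participant i
# always receives the i-th element of each block), so identical configs give
# byte-identical cohorts and row order never changes any draw.

#' Generate a synthetic cohort
#'
#' Draws a cohort of participants with sex, entry age/date, education,
#' education-conditional mediators (anthropometry, blood pressure, HbA1c,
#' diabetes diagnosis, smoking, alcohol, physical activity, income, area
#' deprivation score) and a simulated death (age and cause group) from the
#' piecewise-constant competing-cause hazard model. Deaths simulated beyond
#' the administrative censoring date are returned censored.
#'
#' @param config A [cohort_config()] object.
#' @return A data frame with one row per participant: identifiers, entry
#'   fields, covariates and the vital-status outcome (`death_date`,
#'   `death_cause`, both `NA` when censored; `cause_uncertain` flag).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 500, seed = 7))
#' table(cohort$education, cohort$sex)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    .stop_config("config must be built with cohort_config()")
  }
  n <- config$n_participants
  hm <- config$hazard_model
  mm <- config$mediator_model
  set.seed(config$seed)

  # -- fixed draw blocks ------------------------------------------------
  sex <- ifelse(stats::runif(n) < config$fraction_male, "male", "female")
  male <- sex == "male"
  ea <- config$entry_age
  entry_age <- round(.rtruncnorm(stats::runif(n), ea$mean, ea$sd,
                                 ea$min, ea$max), 3)
  span <- as.numeric(config$recruitment_window[2] -
                     config$recruitment_window[1])
  entry_date <- config$recruitment_window[1] +
    floor(stats::runif(n) * (span + 1))

  edu_idx <- integer(n)
  u_edu <- stats::runif(n)
  for (s in SEX_LEVELS) {
    i <- sex == s
    p <- matrix(config$education_probs_by_sex[[s]], sum(i), 5, byrow = TRUE)
    edu_idx[i] <- .sample_cat(u_edu[i], p)
  }
  education <- EDU_LEVELS[edu_idx]

  # -- mediators, conditional on (sex, education) -----------------------
  sx_row <- ifelse(male, 1L, 2L)
  pick <- function(mat) mat[cbind(sx_row, edu_idx)]
  by_sex <- function(v) unname(v[ifelse(male, "male", "female")])
  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])

  height <- round(clamp(stats::rnorm(n, by_sex(mm$height$mean),
                                     by_sex(mm$height$sd)),
                        mm$height$range), 1)
  bmi <- clamp(stats::rnorm(n, pick(mm$bmi$mean), by_sex(mm$bmi$sd)),
               mm$bmi$range)
  weight <- round(clamp(bmi * (height / 100)^2, c(36, 245)), 1)
  waist <- round(clamp(stats::rnorm(n, pick(mm$waist$mean),
                                    by_sex(mm$waist$sd)),
                       mm$waist$range), 1)
  whr <- clamp(stats::rnorm(n, by_sex(mm$whr$mean), by_sex(mm$whr$sd)),
               mm$whr$range)
  hip <- round(clamp(waist / whr, c(71, 179)), 1)
  sbp <- round(clamp(stats::rnorm(n, pick(mm$sbp$mean), by_sex(mm$sbp$sd)),
                     mm$sbp$range), 1)
  dbp <- round(clamp(stats::rnorm(n, pick(mm$dbp$mean), by_sex(mm$dbp$sd)),
                     mm$dbp$range), 1)
  diabetes_diagnosed <- stats::runif(n) < pick(mm$diabetes_diagnosed$prob)
  hba1c_base <- clamp(stats::rnorm(n, pick(mm$hba1c$mean),
                                   by_sex(mm$hba1c$sd)),
                      mm$hba1c$range)
  hba1c_diag <- clamp(stats::rnorm(n, mm$hba1c$diagnosed_mean,
                                   mm$hba1c$diagnosed_sd),
                      mm$hba1c$diagnosed_range)
  hba1c <- round(ifelse(diabetes_diagnosed, hba1c_diag, hba1c_base), 1)

  draw_cat <- function(block, levels) {
    u <- stats::runif(n)
    out <- character(n)
    for (s in SEX_LEVELS) {
      i <- sex == s
      out[i] <- levels[.sample_cat(u[i], block[[s]][edu_idx[i], , drop = FALSE])]
    }
    out
  }
  smoking <- draw_cat(mm$smoking$prob, SMOKING_LEVELS)
  alcohol <- draw_cat(mm$alcohol$prob, ALCOHOL_LEVELS)
  activity <- draw_cat(mm$activity$prob, ACTIVITY_LEVELS)

  none_inc <- stats::runif(n) < pick(mm$income$p_none)
  mu <- pick(mm$income$mean)
  meanlog <- log(mu) - mm$income$sdlog^2 / 2
  income <- round(ifelse(none_inc, 0,
                         clamp(stats::rlnorm(n, meanlog, mm$income$sdlog),
                               c(50, 2e5))))
  sdi <- round(clamp(stats::rnorm(n, pick(mm$sdi$mean), mm$sdi$sd),
                     mm$sdi$range), 3)

  # -- linear predictors and event simulation ---------------------------
  diabetes_cat <- .diabetes_category(diabetes_diagnosed, hba1c)
  lp_med <- .mediator_lp(hm$mediator_coef,
                         data.frame(sbp = sbp, weight = weight,
                                    waist = waist, hip = hip,
                                    smoking = smoking, alcohol = alcohol,
                                    activity = activity,
                                    diabetes = diabetes_cat))
  lp <- .education_lp(hm, edu_idx) + lp_med

  E <- stats::rexp(n)
  u_cause <- stats::runif(n)
  ev <- .sim_event_times(entry_age, sex, lp, hm, E, u_cause)

  death_date <- entry_date + round((ev$event_age - entry_age) * 365.25)
  died <- !is.na(ev$event_age) & death_date <= config$admin_censor_date
  death_date[!died] <- NA
  death_cause <- ifelse(died, ev$cause, NA_character_)

  data.frame(
    id = sprintf("P%07d", seq_len(n)),
    sex = sex, entry_age = entry_age, entry_date = entry_date,
    education = education, income_monthly = income, sdi = sdi,
    smoking = smoking, alcohol = alcohol, activity = activity,
    height = height, weight = weight, waist = waist, hip = hip,
    sbp = sbp, dbp = dbp, hba1c = hba1c,
    diabetes_diagnosed = diabetes_diagnosed,
    death_date = death_date, death_cause = death_cause,
    cause_uncertain = FALSE,
    stringsAsFactors = FALSE)
}

# Per-cause linear predictor from the direct education effect: n x C matrix.
.education_lp <- function(hm, edu_idx) {
  C <- length(hm$causes)
  if (is.matrix(hm$education_logrr)) {
    t(hm$education_logrr[, edu_idx, drop = FALSE])
  } else {
    matrix(hm$education_logrr[edu_idx], length(edu_idx), C)
  }
}

# Scalar mediator contribution to the log hazard (shared across causes).
.mediator_lp <- function(coef, d) {
  if (is.null(coef)) return(numeric(nrow(d)))
  lp <- numeric(nrow(d))
  for (v in names(coef$continuous)) {
    lp <- lp + coef$continuous[[v]] * (d[[v]] - coef$centers[[v]])
  }
  for (v in c("smoking", "alcohol", "activity", "diabetes")) {
    cv <- coef[[v]]
    if (is.null(cv)) next
    m <- match(d[[v]], names(cv))
    lp <- lp + ifelse(is.na(m), 0, cv[m])
  }
  lp
}

.diabetes_category <- function(diagnosed, hba1c) {
  out <- rep(NA_character_, length(diagnosed))
  known <- !is.na(hba1c)
  out[!diagnosed & known & hba1c <= 6.5] <- "none"
  out[!diagnosed & known & hba1c > 6.5] <- "undiagnosed"
  out[diagnosed & known & hba1c < 9] <- "diagnosed_hba1c_lt9"
  out[diagnosed & known & hba1c >= 9 & hba1c < 11] <- "diagnosed_hba1c_9_11"
  out[diagnosed & known & hba1c >= 11] <- "diagnosed_hba1c_ge11"
  out
}

#' Simulate competing-cause event times under a piecewise-constant hazard
#'
#' Draws event ages by exact inversion of the cumulative total hazard
#' (piecewise constant on the model's age bands), then draws the cause of
#' death with probability proportional to the cause-specific hazard at the
#' event age. Vectorised over participants; uses the current RNG state.
#'
#' @param entry_age Numeric vector of entry ages (years), within the hazard
#'   grid.
#' @param sex Character vector, `"male"`/`"female"`.
#' @param linear_predictors_by_cause Numeric matrix (participants x causes)
#'   of log hazard-rate multipliers, or a single row recycled.
#' @param hazard_model A [hazard_model()] object.
#' @return A data frame with `event_age` (`NA` if no event occurs within the
#'   hazard grid) and `cause` (`NA` likewise).
#' @examples
#' hm <- hazard_model()
#' set.seed(1)
#' simulate_event_time(c(40, 60), c("male", "female"),
#'                     matrix(0, 2, length(hm$causes)), hm)
#' @export
simulate_event_time <- function(entry_age, sex, linear_predictors_by_cause,
                                hazard_model) {
  hm <- hazard_model
  if (!inherits(hm, "hazard_model")) {
    .stop_config("hazard_model must be built with hazard_model()")
  }
  n <- length(entry_age)
  lp <- linear_predictors_by_cause
  if (is.null(dim(lp))) lp <- matrix(lp, n, length(hm$causes), byrow = TRUE)
  if (any(!is.finite(lp))) .stop_config("linear predictors must be finite")
  if (any(entry_age < hm$age_breaks[1]) ||
      any(entry_age >= hm$age_breaks[length(hm$age_breaks)])) {
    .stop_config("entry_age outside the hazard grid")
  }
  .sim_event_times(entry_age, sex, lp, hm,
                   stats::rexp(n), stats::runif(n))
}

.sim_event_times <- function(entry_age, sex, lp, hm, E, u_cause) {
  n <- length(entry_age)
  breaks <- hm$age_breaks
  B <- length(breaks) - 1L
  elp <- exp(lp)

  tot <- matrix(0, n, B)                      # total hazard per band
  for (s in SEX_LEVELS) {
    i <- sex == s
    if (any(i)) tot[i, ] <- elp[i, , drop = FALSE] %*% hm$baseline[[s]]
  }

  # time-at-risk within each band, given entry age
  lo <- matrix(breaks[-(B + 1L)], n, B, byrow = TRUE)
  hi <- matrix(breaks[-1L], n, B, byrow = TRUE)
  w <- pmax(0, hi - pmax(lo, entry_age))
  H <- tot * w

  cum <- H
  for (b in seq_len(B)[-1]) cum[, b] <- cum[, b - 1] + cum[, b]
  k <- rowSums(cum < E) + 1L                  # first band where cum >= E
  has_event <- k <= B

  event_age <- rep(NA_real_, n)
  cause <- rep(NA_character_, n)
  if (any(has_event)) {
    i <- which(has_event)
    ki <- k[i]
    prev <- ifelse(ki > 1L, cum[cbind(i, pmax(ki - 1L, 1L))], 0)
    rate <- tot[cbind(i, ki)]
    start_k <- pmax(breaks[ki], entry_age[i])
    event_age[i] <- start_k + (E[i] - prev) / rate

    # cause ~ cause-specific hazard at the event age
    pc <- elp[i, , drop = FALSE]
    for (s in SEX_LEVELS) {
      j <- sex[i] == s
      if (any(j)) {
        pc[j, ] <- pc[j, , drop = FALSE] *
          t(hm$baseline[[s]])[ki[j], , drop = FALSE]
      }
    }
    cp <- pc
    for (cc in seq_len(ncol(pc))[-1]) cp[, cc] <- cp[, cc - 1] + pc[, cc]
    thr <- u_cause[i] * cp[, ncol(cp)]
    idx <- rowSums(cp < thr) + 1L
    cause[i] <- hm$causes[pmin(idx, length(hm$causes))]
  }
  data.frame(event_age = event_age, cause = cause, stringsAsFactors = FALSE)
}

#' Inject quality-control defects into a clean cohort
#'
#' Makes the requested numbers of rows ineligible, each row by exactly one
#' defect class, on disjoint row sets: `n_overage` rows get an entry age of
#' 85 or above, `n_missing` rows lose their education value, `n_extreme`
#' rows get one anthropometric measurement pushed past an exclusion
#' threshold (for example height below 120 cm), and `n_uncertain` rows are
#' flagged as having uncertain mortality linkage. Used to exercise the
#' sequential exclusion ledger of [apply_exclusions()].
#'
#' @param cohort A cohort data frame.
#' @param n_overage,n_missing,n_extreme,n_uncertain Defect counts.
#' @param seed Integer seed for row selection.
#' @return The modified cohort.
#' @export
inject_defects <- function(cohort, n_overage, n_missing, n_extreme,
                           n_uncertain, seed = 1L) {
  counts <- c(n_overage, n_missing, n_extreme, n_uncertain)
  if (any(counts < 0) || sum(counts) > nrow(cohort)) {
    stop("defect counts must be non-negative and sum to at most nrow(cohort)",
         call. = FALSE)
  }
  if (sum(counts) == 0) return(cohort)
  set.seed(seed)
  rows <- sample.int(nrow(cohort), sum(counts))
  take <- function(k) {
    out <- rows[seq_len(k)]
    rows <<- rows[-seq_len(k)]
    out
  }
  i <- take(n_overage)
  cohort$entry_age[i] <- round(85 + stats::runif(n_overage) * 10, 3)
  i <- take(n_missing)
  cohort$education[i] <- NA_character_
  i <- take(n_extreme)
  if (n_extreme > 0) {
    fields <- sample(c("height_low", "height_high", "weight_low",
                       "waist_high"), n_extreme, replace = TRUE)
    cohort$height[i[fields == "height_low"]] <- 112
    cohort$height[i[fields == "height_high"]] <- 207
    cohort$weight[i[fields == "weight_low"]] <- 31
    cohort$waist[i[fields == "waist_high"]] <- 186
  }
  i <- take(n_uncertain)
  cohort$cause_uncertain[i] <- TRUE
  cohort
}
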