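one_subject <- function(entry_age, death_years = NA, sex = "male",
                        entry_date = as.Date("2000-01-01")) {
  data.frame(id = "s1", sex = sex, entry_age = entry_age,
             entry_date = entry_date,
             death_date = if (is.na(death_years)) as.Date(NA) else
               entry_date + round(death_years * 365.25),
             death_cause = if (is.na(death_years)) NA_character_ else
               "cardiac",
             education = "none", stringsAsFactors = FALSE)
}

test_that("a traversing subject is split across the right bands", {
  # entry 48.3, death at age 61.0: bands 45-49, 50-54, 55-59, 60-64
  d <- one_subject(48.3, death_years = 61.0 - 48.3)
  rec <- lexis_split(d, admin_censor_date = as.Date("2030-01-01"))
  expect_equal(rec$age_band, c("45-49", "50-54", "55-59", "60-64"))
  expect_equal(sum(rec$t_stop - rec$t_start), 61.0 - 48.3, tolerance = 0.01)
  expect_equal(rec$event, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(rec$stratum, paste0("male:", rec$age_band))
})

test_that("deaths at or past the age cap are censored at the cap", {
  d <- one_subject(70, death_years = 6)   # death at age 76
  rec <- lexis_split(d, age_max = 75, admin_censor_date = as.Date("2030-01-01"))
  expect_false(any(rec$event))
  expect_equal(max(rec$t_stop), 75 - 70)  # censored at the 75th birthday
})

test_that("short follow-up stays within a single band", {
  d <- one_subject(40.0)
  rec <- lexis_split(d, admin_censor_date = as.Date("2000-01-01") +
                       round(4.9 * 365.25))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$age_band, "40-44")
  expect_false(rec$event)
})

test_that("a death exactly on a band boundary belongs to the older band", {
  # 4 whole years = 1461 days exactly, so entry at 56 gives death age 60.0
  d <- one_subject(56, death_years = 4)
  rec <- lexis_split(d, admin_censor_date = as.Date("2030-01-01"))
  ev <- rec[rec$event, ]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$age_band, "60-64")
  expect_equal(ev$t_start, ev$t_stop)     # degenerate boundary record
  # and the engine still counts the death in an estimable fit
  d2 <- rbind(
    cbind(one_subject(56, death_years = 4), x = 1),
    cbind(one_subject(56, death_years = 6), x = 0),
    cbind(one_subject(57, death_years = NA), x = 0),
    cbind(one_subject(58, death_years = 3), x = 1))
  d2$id <- paste0("s", 1:4)
  rec2 <- lexis_split(d2, admin_censor_date = as.Date("2030-01-01"))
  expect_equal(sum(rec2$event), 3)
  # 4 subjects is too small for a stable estimate (separation is expected);
  # the point is that the degenerate record does not break the likelihood
  fit <- suppressWarnings(fit_stratified_cox(rec2, "x"))
  expect_true(is.finite(fit$loglik))
})

test_that("person-time and deaths are conserved through the split", {
  cc <- recovery_config(4000, seed = 21)
  cohort <- generate_cohort(cc)
  rec <- suppressWarnings(lexis_split(cohort, admin_censor_date =
                                        cc$admin_censor_date))
  # independent accounting of expected person-time and events
  age_censor <- cohort$entry_age +
    as.numeric(cc$admin_censor_date - cohort$entry_date) / 365.25
  death_age <- cohort$entry_age +
    as.numeric(cohort$death_date - cohort$entry_date) / 365.25
  exit <- pmin(age_censor, 75)
  exit[!is.na(death_age)] <- pmin(exit, death_age)[!is.na(death_age)]
  entry_eff <- pmax(cohort$entry_age, 35)
  expect_equal(sum(rec$t_stop - rec$t_start),
               sum(pmax(0, exit - entry_eff)), tolerance = 1e-9)
  expect_equal(sum(rec$event),
               sum(!is.na(death_age) & death_age < 75 &
                     death_age >= entry_eff & death_age <= age_censor))
  # ages at t_start lie within the stratum's band
  band_lo <- as.numeric(sub("-.*", "", rec$age_band))
  age_at_start <- cohort$entry_age[match(rec$id, cohort$id)] + rec$t_start
  expect_true(all(age_at_start >= band_lo - 1e-9 &
                    age_at_start < band_lo + 5))
})

test_that("cause-specific preparation censors other-cause deaths", {
  d <- do.call(rbind, lapply(1:5, function(i) {
    r <- one_subject(50 + i, death_years = 3)
    r$id <- paste0("s", i)
    r
  }))
  d$death_cause <- c("cardiac", "stroke", "cardiac", "cancer", "cancer")
  rec <- lexis_split(d, admin_censor_date = as.Date("2030-01-01"))
  expect_identical(prepare_cause(rec, "all"), rec)

  vas <- prepare_cause(rec, "vascular")
  expect_equal(sum(vas$event), 3)          # cardiac + stroke
  expect_equal(sum(vas$t_stop - vas$t_start),
               sum(rec$t_stop - rec$t_start))  # person-time unchanged

  expect_error(prepare_cause(rec, "homicide"), "known groups")
})

test_that("cause-specific events sum to all-cause events over a partition", {
  cc <- cohort_config(n_participants = 4000, seed = 33)
  rec <- split_cohort(cc)
  disjoint <- c("cardiac", "stroke", "hepatobiliary",
                "renal_and_acute_diabetic", "cancer", "respiratory",
                "infectious", "other")
  by_cause <- vapply(disjoint,
                     function(cs) sum(prepare_cause(rec, cs)$event),
                     numeric(1))
  expect_equal(sum(by_cause), sum(rec$event))
})
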