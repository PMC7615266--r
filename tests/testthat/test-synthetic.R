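test_that("identical config and seed give byte-identical cohorts", {
  cc <- cohort_config(n_participants = 2000, seed = 42)
  expect_identical(generate_cohort(cc), generate_cohort(cc))
})

test_that("education marginals by sex converge to the configured shares", {
  cc <- cohort_config(n_participants = 50000, seed = 5)
  cohort <- generate_cohort(cc)
  for (s in c("male", "female")) {
    sub <- cohort$education[cohort$sex == s]
    n <- length(sub)
    p_hat <- as.numeric(table(factor(sub, education_levels())) / n)
    p <- cc$education_probs_by_sex[[s]]
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(p_hat - p) <= 3 * se),
                info = paste("education marginals,", s))
  }
})

test_that("zero baseline hazard yields a fully censored cohort", {
  hm <- hazard_model()
  for (s in c("male", "female")) hm$baseline[[s]][] <- 0
  cc <- cohort_config(n_participants = 500, seed = 1, hazard_model = hm)
  cohort <- generate_cohort(cc)
  expect_true(all(is.na(cohort$death_date)))
  expect_true(all(is.na(cohort$death_cause)))
})

test_that("no simulated death survives past the administrative censor date", {
  cohort <- generate_cohort(cohort_config(n_participants = 5000, seed = 9))
  died <- !is.na(cohort$death_date)
  expect_true(all(cohort$death_date[died] <= as.Date("2020-12-31")))
  expect_true(all(cohort$death_date[died] >= cohort$entry_date[died]))
  # exactly one of death / censoring per participant
  expect_identical(is.na(cohort$death_date), is.na(cohort$death_cause))
})

test_that("constant-hazard event times are exponential with the right mean", {
  # single cause, lambda = 0.02/yr on an unbounded-in-practice grid
  br <- seq(35, 35 + 5 * 200, by = 5)
  base <- matrix(0.02, 1, length(br) - 1)
  hm <- hazard_model(age_breaks = br, causes = "all_cause",
                     baseline = list(male = base, female = base),
                     mediator_coef = NULL)
  n <- 100000
  set.seed(31)
  ev <- simulate_event_time(rep(35, n), rep("male", n),
                            matrix(0, n, 1), hm)
  expect_true(all(!is.na(ev$event_age)))
  expect_equal(mean(ev$event_age), 35 + 1 / 0.02,
               tolerance = 3 * (1 / 0.02) / sqrt(n) / (35 + 50))
})

test_that("competing causes are drawn in proportion to their hazards", {
  br <- seq(35, 35 + 5 * 200, by = 5)
  lam <- 0.01
  base <- rbind(c1 = rep(lam, length(br) - 1), c2 = rep(2 * lam, length(br) - 1))
  hm <- hazard_model(age_breaks = br, causes = c("c1", "c2"),
                     baseline = list(male = base, female = base),
                     mediator_coef = NULL)
  n <- 50000
  set.seed(7)
  ev <- simulate_event_time(rep(40, n), rep("female", n),
                            matrix(0, n, 2), hm)
  share2 <- mean(ev$cause == "c2")
  expect_lt(abs(share2 - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / n))
})

test_that("doubling all baseline rates halves the median time to event", {
  br <- seq(35, 35 + 5 * 400, by = 5)
  mk <- function(lam) {
    base <- matrix(lam, 1, length(br) - 1)
    hazard_model(age_breaks = br, causes = "x",
                 baseline = list(male = base, female = base),
                 mediator_coef = NULL)
  }
  n <- 50000
  set.seed(12)
  E <- rexp(n); U <- runif(n)                 # common uniforms for the pair
  t1 <- edumort:::.sim_event_times(rep(35, n), rep("male", n),
                                   matrix(0, n, 1), mk(0.01), E, U)
  t2 <- edumort:::.sim_event_times(rep(35, n), rep("male", n),
                                   matrix(0, n, 1), mk(0.02), E, U)
  m1 <- median(t1$event_age - 35)
  m2 <- median(t2$event_age - 35)
  expect_equal(m1 / m2, 2, tolerance = 1e-10)  # exact under shared draws
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_participants = 0), "positive integer")
  expect_error(cohort_config(education_probs_by_sex = list(
    male = c(0.5, 0.2, 0.1, 0.1, 0.3), female = rep(0.2, 5))), "sums to")
  base <- matrix(-0.01, 8, 14)
  expect_error(hazard_model(baseline = list(male = base, female = base)),
               "negative")
  hm <- hazard_model()
  expect_error(simulate_event_time(20, "male",
                                   matrix(0, 1, length(hm$causes)), hm),
               "hazard grid")
})

test_that("inject_defects creates exactly the requested defects", {
  cohort <- generate_cohort(cohort_config(n_participants = 1000, seed = 3))
  expect_identical(inject_defects(cohort, 0, 0, 0, 0), cohort)

  bad <- inject_defects(cohort, 10, 5, 3, 2, seed = 8)
  expect_equal(sum(bad$entry_age >= 85), 10)
  expect_equal(sum(is.na(bad$education)), 5)
  extreme <- (bad$height < 120 | bad$height > 200 | bad$weight < 35 |
                bad$waist > 180)
  expect_equal(sum(extreme, na.rm = TRUE), 3)
  expect_equal(sum(bad$cause_uncertain), 2)

  expect_error(inject_defects(cohort, 600, 300, 200, 100), "at most")
})
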