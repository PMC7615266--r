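test_that("the maximiser agrees with a brute-force oracle on toy data", {
  d <- toy_single_stratum()
  fit <- fit_stratified_cox(d, "x")
  expect_equal(unname(fit$beta), naive_cox_mle(d, "x"), tolerance = 1e-6)
  expect_equal(fit$loglik, naive_cox_loglik(unname(fit$beta), d, "x"),
               tolerance = 1e-9)
  expect_true(fit$converged)

  d2 <- toy_two_strata()
  fit2 <- fit_stratified_cox(d2, "x", adjustment = "z")
  expect_equal(unname(fit2$beta), naive_cox_mle(d2, c("x", "z")),
               tolerance = 1e-6)
})

test_that("the engine matches survival::coxph to machine precision", {
  library(survival)
  cc <- recovery_config(3000, seed = 14)
  rec <- split_cohort(cc)
  for (t in c("breslow", "efron")) {
    fit <- fit_stratified_cox(rec, "education_cat", reference = "tertiary",
                              adjustment = "sbp", ties = t)
    cph <- coxph(Surv(t_start, t_stop, event) ~
                   relevel(education_cat, "tertiary") + sbp +
                   strata(stratum),
                 data = rec, ties = t,
                 control = coxph.control(timefix = FALSE))
    expect_equal(unname(fit$beta), unname(coef(cph)), tolerance = 1e-7)
    expect_equal(unname(fit$cov), unname(vcov(cph)), tolerance = 1e-7)
    expect_equal(fit$loglik, cph$loglik[2], tolerance = 1e-7)
  }
})

test_that("degenerate designs are rejected or flagged", {
  d <- toy_single_stratum()
  d$x <- 1
  expect_error(fit_stratified_cox(d, "x"), "constant")

  d2 <- toy_single_stratum()
  d2$event <- FALSE
  expect_error(fit_stratified_cox(d2, "x"), "no events")

  # separation: the exposed level never dies
  d3 <- toy_single_stratum()
  d3$x <- c(0, 1, 0, 0, 1, 0)           # deaths only at x = 0
  expect_warning(fit3 <- fit_stratified_cox(d3, "x"), "separation")
  expect_false(fit3$converged)
  expect_true(abs(unname(fit3$beta)) <= 15)
})

test_that("sex-specific fits equal the combined fit restricted to that sex", {
  cc <- recovery_config(6000, seed = 19)
  rec <- split_cohort(cc)
  men <- rec[rec$sex == "male", ]
  fit_m <- fit_stratified_cox(men, "education_cat", reference = "tertiary")
  # the combined fit's strata are sex x band, so restricting the records to
  # one sex must reproduce that sex's stratum-wise likelihood exactly
  fit_all_m <- fit_stratified_cox(rec[rec$stratum %in% men$stratum, ],
                                  "education_cat", reference = "tertiary")
  expect_equal(fit_m$beta, fit_all_m$beta, tolerance = 1e-10)
  expect_equal(fit_m$loglik, fit_all_m$loglik, tolerance = 1e-10)
})

test_that("estimates recover the simulated education effects", {
  cc <- recovery_config(20000, seed = 27)
  rec <- split_cohort(cc)
  fit <- fit_stratified_cox(rec, "education_cat", reference = "tertiary")
  truth <- log(c(1.8, 1.75, 1.6, 1.35))
  se <- sqrt(diag(fit$cov))
  expect_true(all(abs(unname(fit$beta) - truth) <= 3 * se))
  expect_true(fit$converged)
  expect_lte(fit$iterations, 50)
})

test_that("the rate-ratio table carries reference RR 1 and event counts", {
  cc <- recovery_config(5000, seed = 8)
  rec <- split_cohort(cc)
  fit <- fit_stratified_cox(rec, "education_cat", reference = "tertiary")
  fl <- float_variances(fit)
  tab <- rr_table(fit, fl)
  expect_equal(tab$RR[tab$level == "tertiary"], 1)
  expect_equal(sum(tab$n_events), fit$n_events)
  expect_true(all(tab$lower < tab$RR & tab$RR < tab$upper))
  # without floated variances the reference CI is undefined
  expect_message(tab2 <- rr_table(fit), "conventional")
  expect_true(is.na(tab2$lower[tab2$level == "tertiary"]))
  # the contrast CI is unchanged by floating in the two-level case
  rec$low_edu <- rec$education_cat %in% c("none", "primary_incomplete")
  fit2 <- fit_stratified_cox(rec, "low_edu")
  fl2 <- float_variances(fit2)
  v <- fit2$cov[1, 1]
  expect_equal(sum(fl2$variances), v, tolerance = 1e-10)
})
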