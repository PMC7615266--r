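test_that("calibration reproduces the prevalence-weighted national rate", {
  p <- c(0.07, 0.16, 0.24, 0.27, 0.25)
  r <- c(1.62, 1.67, 1.62, 1.34, 1)
  rates <- calibrate_rates(0.01, p, r)
  A <- 0.01 / sum(p * r)
  expect_equal(unname(rates), r * A, tolerance = 1e-14)
  expect_equal(A, 0.0072401, tolerance = 1e-4)
  expect_equal(sum(p * rates), 0.01, tolerance = 1e-12)

  # degenerate calibration: all RR = 1
  expect_equal(unname(calibrate_rates(0.004, rep(0.2, 5), rep(1, 5))),
               rep(0.004, 5))
  # homogeneity of degree 1 in the national rate
  expect_equal(unname(calibrate_rates(0.02, p, r)), 2 * unname(rates))

  expect_error(calibrate_rates(0.01, c(0.5, 0.2, 0.1, 0.1, 0.2), r),
               "sum to 1")
  expect_error(calibrate_rates(0.01, p, c(1.5, 1.2, 1, 0.8, 0)),
               "positive")
  expect_error(calibrate_rates(-0.01, p, r), "non-negative")
})

test_that("survival curves follow the piecewise-exponential closed forms", {
  S <- survival_curve(rep(0.02, 7), seq(35, 70, 5))
  expect_equal(unname(S[1]), 1)
  expect_equal(unname(S[8]), exp(-0.7), tolerance = 1e-12)

  expect_equal(unname(survival_curve(rep(0, 7), seq(35, 70, 5))), rep(1, 8))

  # componentwise larger rates give pointwise smaller survival
  set.seed(3)
  r1 <- runif(7, 0, 0.05)
  r2 <- r1 + runif(7, 0, 0.02)
  expect_true(all(survival_curve(r2, seq(35, 70, 5)) <=
                    survival_curve(r1, seq(35, 70, 5))))

  expect_error(survival_curve(rep(0.01, 3), c(35, 40, 50, 45)),
               "band coverage")
})

test_that("partial life expectancy matches closed form and quadrature", {
  br <- seq(35, 70, 5)
  S <- survival_curve(rep(0.02, 7), br)
  expect_equal(partial_life_expectancy(S, br), (1 - exp(-0.7)) / 0.02,
               tolerance = 1e-12)
  expect_equal(partial_life_expectancy(survival_curve(rep(0, 7), br), br),
               35)
  # exact within-band integration agrees with a fine numerical oracle
  set.seed(9)
  ra <- runif(7, 0.001, 0.04)
  rb <- runif(7, 0.001, 0.04)
  Sa <- survival_curve(ra, br); Sb <- survival_curve(rb, br)
  diff_exact <- partial_life_expectancy(Sa, br) -
    partial_life_expectancy(Sb, br)
  diff_quad <- quadrature_le(ra, br) - quadrature_le(rb, br)
  expect_equal(diff_exact, diff_quad, tolerance = 1e-6)
})

test_that("projection reduces to the national curve when all RRs are 1", {
  lt <- read_life_table(system.file("extdata", "lifetable_synthetic_mx.csv",
                                    package = "edumort"))
  proj <- project_education_survival(lt, rr = rep(1, 5))
  for (s in c("male", "female")) {
    nat <- lt[lt$sex == s & lt$age_lo < 70, ]
    Snat <- survival_curve(nat$annual_rate, c(nat$age_lo, 70))
    for (e in education_levels()) {
      sv <- proj$survival[proj$survival$sex == s &
                            proj$survival$education == e, ]
      expect_equal(sv$S, unname(Snat), tolerance = 1e-12)
    }
  }
  expect_true(all(abs(proj$life_expectancy$gap_vs_reference) < 1e-10))
})

test_that("projected gaps are antisymmetric and ordered by the RRs", {
  lt <- read_life_table(system.file("extdata", "lifetable_synthetic_mx.csv",
                                    package = "edumort"))
  rr <- c(1.84, 1.78, 1.62, 1.34, 1)
  names(rr) <- education_levels()
  proj <- project_education_survival(lt, rr = rr)
  le <- proj$life_expectancy[proj$life_expectancy$sex == "male", ]
  le_by <- setNames(le$partial_le, le$education)
  # gap antisymmetry
  expect_equal(le_by[["tertiary"]] - le_by[["none"]],
               -(le_by[["none"]] - le_by[["tertiary"]]))
  # higher RR, lower life expectancy
  expect_true(all(diff(le_by[education_levels()]) >= 0))
  expect_true(all(le$gap_vs_reference[le$education != "tertiary"] > 0))
  # prevalence-weighted identity band by band (renormalised default shares)
  p <- c(0.07, 0.16, 0.24, 0.27, 0.25) / 0.99
  for (b in unique(proj$rates$age_lo[proj$rates$sex == "male"])) {
    rt <- proj$rates[proj$rates$sex == "male" & proj$rates$age_lo == b, ]
    nat <- lt$annual_rate[lt$sex == "male" & lt$age_lo == b]
    expect_equal(sum(p * rt$annual_rate[match(education_levels(),
                                              rt$education)]),
                 nat, tolerance = 1e-12)
  }
})

test_that("raising one group's RR is compensated by every other group", {
  # with the national rate held fixed, increasing a single non-reference
  # group's RR lowers that group's life expectancy and (through the anchor
  # rate A) can only raise everyone else's
  lt <- read_life_table(system.file("extdata", "lifetable_synthetic_mx.csv",
                                    package = "edumort"))
  set.seed(11)
  for (rep in 1:5) {
    rr1 <- c(sort(runif(4, 1, 2), decreasing = TRUE), 1)
    k <- sample(1:4, 1)
    rr2 <- rr1
    rr2[k] <- rr2[k] + runif(1, 0.05, 0.5)
    p1 <- project_education_survival(lt, rr = rr1)$life_expectancy
    p2 <- project_education_survival(lt, rr = rr2)$life_expectancy
    for (s in c("male", "female")) {
      le1 <- p1[p1$sex == s, ]; le2 <- p2[p2$sex == s, ]
      raised <- le1$education == education_levels()[k]
      expect_lte(le2$partial_le[raised], le1$partial_le[raised] + 1e-9)
      expect_true(all(le2$partial_le[!raised] >=
                        le1$partial_le[!raised] - 1e-9))
    }
  }
})

test_that("age-range-specific RR vectors apply to their own bands", {
  lt <- read_life_table(system.file("extdata", "lifetable_synthetic_mx.csv",
                                    package = "edumort"))
  rr <- list("35-59" = c(2, 1.8, 1.6, 1.3, 1),
             "60-69" = c(1.5, 1.4, 1.3, 1.2, 1))
  proj <- project_education_survival(lt, rr = rr)
  rts <- proj$rates[proj$rates$sex == "male" &
                      proj$rates$education == "none", ]
  nat <- lt[lt$sex == "male", ]
  ratio <- rts$annual_rate /
    nat$annual_rate[match(rts$age_lo, nat$age_lo)]
  anchor_young <- ratio[rts$age_lo < 60] / 2
  anchor_old <- ratio[rts$age_lo >= 60] / 1.5
  # within each age range the rate/national ratio is RR_none * A-share
  expect_true(all(abs(anchor_young - anchor_young[1]) < 1e-12))
  expect_true(all(abs(anchor_old - anchor_old[1]) < 1e-12))
})
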