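# Simulation scenarios used across the tests. Each scenario fixes the
# generative conditions once; tests only vary n and seed.

# Direct education effects only, no mediator effects on the hazard.
recovery_config <- function(n, seed,
                            logrr = log(c(1.8, 1.75, 1.6, 1.35, 1))) {
  cohort_config(n_participants = n, seed = seed,
                hazard_model = hazard_model(education_logrr = logrr,
                                            mediator_coef = NULL))
}

# Education unrelated to mortality (mediators still education-graded).
null_config <- function(n, seed) {
  recovery_config(n, seed, logrr = rep(0, 5))
}

# Education acts on mortality only through SBP and diabetes status:
# steepened mediator gradients, no direct education term.
mediated_config <- function(n, seed, direct = rep(0, 5)) {
  mm <- default_mediator_model()
  mm$sbp$mean <- rbind(male = c(150, 143, 136, 128, 120),
                       female = c(152, 144, 136, 128, 120))
  colnames(mm$sbp$mean) <- education_levels()
  mm$diabetes_diagnosed$prob <-
    rbind(male = c(0.45, 0.35, 0.25, 0.12, 0.05),
          female = c(0.45, 0.35, 0.25, 0.12, 0.05))
  colnames(mm$diabetes_diagnosed$prob) <- education_levels()
  coef <- list(continuous = c(sbp = 0.025), centers = c(sbp = 130),
               diabetes = c(undiagnosed = 0.8, diagnosed_hba1c_lt9 = 1.0,
                            diagnosed_hba1c_9_11 = 1.3,
                            diagnosed_hba1c_ge11 = 1.6))
  cohort_config(n_participants = n, seed = seed, mediator_model = mm,
                hazard_model = hazard_model(education_logrr = direct,
                                            mediator_coef = coef))
}

# Mediators carry no hazard effect AND no education gradient (every
# education column replaced by the sex-specific average), so mediators are
# independent of both exposure and outcome.
flat_mediator_config <- function(n, seed,
                                 logrr = log(c(1.8, 1.75, 1.6, 1.35, 1))) {
  mm <- default_mediator_model()
  flatten <- function(m) {
    m[] <- rowMeans(m)[row(m)]
    m
  }
  for (v in c("bmi", "waist", "sbp", "dbp", "hba1c")) {
    mm[[v]]$mean <- flatten(mm[[v]]$mean)
  }
  mm$diabetes_diagnosed$prob <- flatten(mm$diabetes_diagnosed$prob)
  for (v in c("smoking", "alcohol", "activity")) {
    for (s in c("male", "female")) {
      p <- mm[[v]]$prob[[s]]
      p[] <- rep(colMeans(p), each = nrow(p))
      mm[[v]]$prob[[s]] <- p
    }
  }
  cohort_config(n_participants = n, seed = seed, mediator_model = mm,
                hazard_model = hazard_model(education_logrr = logrr,
                                            mediator_coef = NULL))
}

# Generate, QC and Lexis-split in one go.
split_cohort <- function(config, age_min = 35, age_max = 75) {
  cohort <- generate_cohort(config)
  cohort <- derive_categories(apply_exclusions(cohort)$cohort)
  suppressWarnings(lexis_split(cohort, age_min = age_min, age_max = age_max,
                               admin_censor_date = config$admin_censor_date))
}

# Small hand-built counting-process datasets for oracle checks.
toy_single_stratum <- function() {
  data.frame(
    t_start = c(0.0, 0.0, 0.5, 1.0, 0.2, 0.0),
    t_stop  = c(2.0, 3.5, 4.0, 2.5, 5.0, 1.5),
    event   = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    stratum = "s1",
    x       = c(1, 0, 1, 0, 0, 1))
}

toy_two_strata <- function() {
  data.frame(
    t_start = c(0, 0, 0.3, 1.1, 0, 0.4, 0, 0, 0.9, 0.1),
    t_stop  = c(1.8, 2.9, 3.3, 4.1, 2.2, 1.9, 2.8, 3.6, 4.4, 1.2),
    event   = c(TRUE, TRUE, FALSE, TRUE, FALSE,
                TRUE, FALSE, TRUE, TRUE, FALSE),
    stratum = rep(c("a", "b"), each = 5),
    x       = c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0),
    z       = c(0.2, -0.5, 1.1, 0.7, -0.3, 0.9, -1.2, 0.4, 0.0, 1.5))
}
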