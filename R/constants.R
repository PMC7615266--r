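# Category vocabularies shared across the pipeline.

EDU_LEVELS <- c("none", "primary_incomplete", "primary_complete",
                "secondary", "tertiary")

SEX_LEVELS <- c("male", "female")

SMOKING_LEVELS <- c("never", "former", "occasional",
                    "current_lt10", "current_ge10")

ALCOHOL_LEVELS <- c("never", "former", "lt_weekly",
                    "upto_2_per_week", "gt_2_per_week")

ACTIVITY_LEVELS <- c("none", "upto_twice_weekly", "ge_three_weekly")

DIABETES_LEVELS <- c("none", "undiagnosed", "diagnosed_hba1c_lt9",
                     "diagnosed_hba1c_9_11", "diagnosed_hba1c_ge11")

INCOME_LEVELS <- c("no_income", "lt_1500", "1500_to_lt3000",
                   "3000_to_lt4500", "ge_4500")

# Disjoint cause groups carried on simulated death records. "vascular" is a
# composite of cardiac and stroke deaths.
CAUSE_BASE <- c("cardiac", "stroke", "hepatobiliary",
                "renal_and_acute_diabetic", "cancer", "respiratory",
                "infectious", "other")

.cause_groups <- function() {
  g <- as.list(CAUSE_BASE)
  names(g) <- CAUSE_BASE
  c(list(all = CAUSE_BASE, vascular = c("cardiac", "stroke")), g)
}

#' Category vocabularies used by the pipeline
#'
#' @return `education_levels()` returns the five schooling-phase categories
#'   (none, incomplete primary, complete primary, secondary, tertiary) in
#'   increasing order; `cause_vocabulary()` the registered cause-of-death
#'   group tokens accepted by [prepare_cause()] and [run_pipeline()].
#' @export
education_levels <- function() EDU_LEVELS

#' @rdname education_levels
#' @export
cause_vocabulary <- function() names(.cause_groups())
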