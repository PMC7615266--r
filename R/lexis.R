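# Lexis expansion: split follow-up into age-at-risk bands on the
# time-since-entry timescale, with delayed entry and administrative
# censoring; cause-specific event preparation.

#' Split follow-up into 5-year age-at-risk bands
#'
#' Expands each participant's follow-up into one record per age band
#' traversed between `max(entry_age, age_min)` and the exit age, where exit
#' age is the earliest of the death age, the age at the administrative
#' censoring date, and `age_max`. The timescale of the resulting records is
#' time since study entry; the age band only labels the stratum. Bands are
#' half-open `[a, a + band_width)`; a death occurring exactly on a band
#' boundary belongs to the older band. Person-time and deaths are exactly
#' conserved. Deaths at or after `age_max` are censored at `age_max` and
#' contribute no event.
#'
#' @param cohort A cohort data frame with `entry_age`, `entry_date`,
#'   `death_date`, `death_cause` and `sex`; all other columns are carried
#'   through to the split records.
#' @param age_min,age_max Age-at-risk window in years (default 35-74, i.e.
#'   premature mortality; use 75/85 for the older window).
#' @param band_width Age band width in years.
#' @param admin_censor_date Administrative censoring date (`Date`).
#' @return A data frame of survival records: `id`, `sex`, `age_band`,
#'   `stratum` (sex x age band), `t_start`, `t_stop` (years since entry),
#'   `event`, `death_cause` (on event records), plus all carried covariate
#'   columns. Participants whose follow-up ends before entering the window
#'   contribute no records.
#' @export
lexis_split <- function(cohort, age_min = 35, age_max = 75, band_width = 5,
                        admin_censor_date = as.Date("2020-12-31")) {
  if ((age_max - age_min) %% band_width != 0 || age_max <= age_min) {
    .stop_config("age window must be a whole number of bands")
  }
  admin_censor_date <- as.Date(admin_censor_date)
  w <- band_width
  nb <- as.integer((age_max - age_min) / w)

  entry_age <- cohort$entry_age
  age_censor <- entry_age +
    as.numeric(admin_censor_date - cohort$entry_date) / 365.25
  died <- !is.na(cohort$death_date)
  death_age <- rep(NA_real_, nrow(cohort))
  death_age[died] <- entry_age[died] +
    as.numeric(cohort$death_date[died] - cohort$entry_date[died]) / 365.25

  exit_age <- pmin(age_censor, age_max)
  exit_age[died] <- pmin(exit_age[died], death_age[died])
  is_event <- died & death_age < age_max & death_age <= age_censor

  entry_eff <- pmax(entry_age, age_min)
  keep <- exit_age > entry_eff | (is_event & death_age >= entry_eff)
  # recruits at or above age_max simply contribute no person-time to this
  # window; an exit before entry at in-window ages indicates defective data
  n_skip <- sum(!keep & exit_age < entry_eff & entry_age < age_max)
  if (n_skip > 0) {
    warning(n_skip, " participant(s) exited before entering the age window",
            call. = FALSE)
  }
  idx0 <- which(keep)
  if (!length(idx0)) stop("no participants contribute person-time",
                          call. = FALSE)

  k0 <- pmax(floor((entry_eff[idx0] - age_min) / w), 0)
  k1 <- pmin(floor((exit_age[idx0] - age_min) / w), nb - 1L)
  k_death <- rep(NA_real_, length(idx0))
  ev0 <- is_event[idx0]
  k_death[ev0] <- floor((death_age[idx0][ev0] - age_min) / w)
  # a death exactly on the upper window edge is not an event (handled
  # above); a death exactly on an interior boundary selects the older band
  k1 <- pmax(k1, ifelse(is.na(k_death), k1, k_death))

  times <- as.integer(k1 - k0 + 1L)
  idx <- rep(idx0, times)
  k <- sequence(times) - 1L + rep(k0, times)

  lo_age <- pmax(age_min + k * w, entry_eff[idx])
  hi_age <- pmin(age_min + (k + 1) * w, exit_age[idx])
  ev <- rep(ev0, times) & k == rep(k_death, times) &
    !is.na(rep(k_death, times))
  keep2 <- hi_age > lo_age | ev
  idx <- idx[keep2]; k <- k[keep2]
  lo_age <- lo_age[keep2]; hi_age <- hi_age[keep2]; ev <- ev[keep2]

  band <- sprintf("%d-%d", age_min + k * w, age_min + (k + 1) * w - 1)
  carry <- setdiff(names(cohort),
                   c("entry_date", "death_date", "death_cause"))
  out <- cohort[idx, carry, drop = FALSE]
  out$age_band <- band
  out$stratum <- paste(cohort$sex[idx], band, sep = ":")
  out$t_start <- lo_age - entry_age[idx]
  out$t_stop <- hi_age - entry_age[idx]
  out$event <- ev
  out$death_cause <- ifelse(ev, cohort$death_cause[idx], NA_character_)
  rownames(out) <- NULL
  out
}

#' Prepare records for a cause-specific analysis
#'
#' Keeps the event flag only for deaths from the named cause group; deaths
#' from any other cause become censorings at the same time (person-time is
#' unchanged). `"all"` leaves the events untouched; `"vascular"` is the
#' composite of cardiac and stroke deaths.
#'
#' @param records Survival records from [lexis_split()].
#' @param cause A cause-group token from [cause_vocabulary()].
#' @return The records with the event flag restricted to the cause group.
#' @export
prepare_cause <- function(records, cause) {
  groups <- .cause_groups()
  if (!is.character(cause) || length(cause) != 1 ||
      !cause %in% names(groups)) {
    stop("unknown cause group ", deparse(cause), "; known groups: ",
         paste(names(groups), collapse = ", "), call. = FALSE)
  }
  if (cause == "all") return(records)
  records$event <- records$event & !is.na(records$death_cause) &
    records$death_cause %in% groups[[cause]]
  records
}
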