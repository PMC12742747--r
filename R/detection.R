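# Detection: all routes from an undiagnosed tumour to diagnosis.
# Diagnosis factorises as attendance (being seen) times detection (the
# clinician recognising the lesion); false positives attach to attendance
# events in melanoma-free skin.

#' Organised screening policy
#'
#' @param age_range Two ages; rounds are offered while the attendee's age
#'   is inside `[age_range[1], age_range[2]]`.
#' @param risk_groups Character vector of eligible risk-group labels, or
#'   `NULL` for no risk filter.
#' @param start_year First calendar year of the programme.
#' @param interval Years between rounds (> 0).
#' @param sensitivity Probability of detecting a present melanoma given
#'   attendance, before histology/dwell/site/period modifiers.
#' @param specificity Probability of no false positive in a melanoma-free
#'   attendee.
#' @param participation Probability of attending any given round.
#' @return An object of class `mel_policy`.
#' @export
screening_policy <- function(age_range = c(40, 75), risk_groups = NULL,
                             start_year = 2010, interval = 1,
                             sensitivity = 0.9, specificity = 0.97,
                             participation = 0.6) {
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2],
            interval > 0,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            participation >= 0, participation <= 1)
  structure(list(age_range = as.numeric(age_range),
                 risk_groups = risk_groups,
                 start_year = as.numeric(start_year),
                 interval = as.numeric(interval),
                 sensitivity = sensitivity, specificity = specificity,
                 participation = participation),
            class = "mel_policy")
}

#' @export
print.mel_policy <- function(x, ...) {
  cat("<mel_policy> ages", x$age_range[1], "-", x$age_range[2],
      "| from", x$start_year, "every", x$interval, "y | sens",
      x$sensitivity, "spec", x$specificity, "part", x$participation, "\n")
  invisible(x)
}

# Bounded multiplicative calendar ramp used for uptake growth and the
# diagnostic-technology (dermoscopy-era) period effect.
.calendar_ramp <- function(year, block) {
  f <- pmin(pmax((year - block$start_year) /
                   max(block$end_year - block$start_year, 1e-12), 0), 1)
  block$start_factor + f * (block$end_factor - block$start_factor)
}

#' Skin-check uptake hazard
#'
#' Rate of starting routine skin checks, by age, sex, risk group and
#' calendar year. Only defined before the first melanoma diagnosis (skin
#' checks after diagnosis are surveillance, not screening).
#'
#' @param age Age(s) in years.
#' @param sex `"male"` or `"female"`.
#' @param risk_group Risk-group label or list.
#' @param calendar_year Calendar year(s).
#' @param params A `mel_parameters` object.
#' @param diagnosed Set `TRUE` to signal (erroneously) calling this after
#'   a first diagnosis; raises an error.
#' @return Rate(s) per person-year.
#' @export
uptake_hazard <- function(age, sex, risk_group, calendar_year, params,
                          diagnosed = FALSE) {
  if (isTRUE(diagnosed))
    stop("uptake is only defined before the first melanoma diagnosis")
  rg <- if (is.character(risk_group)) .risk_group(params, risk_group)
        else risk_group
  up <- params$uptake_model
  base <- up$rates[pmin(pmax(findInterval(age, up$age_breaks), 1L),
                        length(up$rates))]
  sf <- if (sex == "female") up$female_factor else 1
  base * sf * rg$uptake_multiplier * .calendar_ramp(calendar_year,
                                                    up$calendar)
}

# Uptake hazard as a pc_hazard in age for one individual (calendar year =
# birth_year + age, so the calendar ramp is a deterministic function of
# age; merge age-band and calendar-ramp breakpoints).
.uptake_pc <- function(params, sex, birth_year, rg) {
  up <- params$uptake_model
  cal <- up$calendar
  brk <- sort(unique(c(up$age_breaks,
                       pmin(pmax(cal$start_year - birth_year,
                                 up$age_breaks[1]),
                            max(up$age_breaks)),
                       pmin(pmax(cal$end_year - birth_year,
                                 up$age_breaks[1]),
                            max(up$age_breaks)))))
  # the ramp is linear between its breakpoints; use the segment-average
  lo <- utils::head(brk, -1L); hi <- brk[-1L]
  mid <- lo + diff(brk) / 2
  base <- up$rates[pmin(pmax(findInterval(mid, up$age_breaks), 1L),
                        length(up$rates))]
  sf <- if (sex == "female") up$female_factor else 1
  ramp_avg <- (.calendar_ramp(birth_year + lo, cal) +
                 .calendar_ramp(birth_year + hi, cal)) / 2
  pc_hazard(brk, base * sf * rg$uptake_multiplier * ramp_avg)
}

#' Routine skin-check attendance probability
#'
#' Compliance with scheduled routine checks decays exponentially with
#' time since uptake (no decay when the decay rate is 0).
#'
#' @param time_since_uptake Years since the uptake event (>= 0).
#' @param params A `mel_parameters` object.
#' @return Probability in \[0,1\], non-increasing in time.
#' @export
attendance_probability <- function(time_since_uptake, params) {
  if (any(time_since_uptake < 0)) stop("time_since_uptake must be >= 0")
  att <- params$attendance
  pmin(pmax(att$initial * exp(-att$decay_rate * time_since_uptake), 0), 1)
}

#' Opportunistic clinician-visit hazard
#'
#' Background rate of clinician contacts at which a skin assessment can
#' happen, by age and sex, scaled up after melanoma emergence by a
#' symptom-prompted presentation boost. Symptoms track the tumour's
#' biological progression, so when the histology is known the boost
#' grows with the fraction of that histology's progression span already
#' elapsed (a nodular melanoma prompts presentation within months, a
#' lentigo maligna only after years); without a histology the boost
#' grows with raw dwell over a configured horizon.
#'
#' @param age Age(s) in years.
#' @param sex `"male"` or `"female"`.
#' @param risk_group Risk-group label or list (kept in the signature for
#'   symmetry; the default fixture does not vary visits by risk).
#' @param time_since_emergence Years since emergence, or `NA`/`NULL` for
#'   a well individual.
#' @param params A `mel_parameters` object.
#' @param histology Optional histology code of the undiagnosed tumour;
#'   scales the symptom boost by progression rather than raw dwell.
#' @return Rate(s) per person-year.
#' @export
visit_hazard <- function(age, sex, risk_group = "average",
                         time_since_emergence = NULL, params,
                         histology = NULL) {
  vr <- params$visit_rates
  base <- vr$rates[pmin(pmax(findInterval(age, vr$age_breaks), 1L),
                        length(vr$rates))]
  sf <- if (sex == "female") vr$female_factor else 1
  boost <- 1
  if (!is.null(time_since_emergence) && !all(is.na(time_since_emergence))) {
    tse <- ifelse(is.na(time_since_emergence), 0, time_since_emergence)
    span <- if (!is.null(histology))
      params$stage_schedules[[histology]]$thresholds$IV
    else vr$boost_cap_years
    boost <- 1 + vr$emergence_boost * pmin(tse / span, 1)
  }
  base * sf * boost
}

# Dwell-dependent per-check detection curve for one histology.
.detection_curve <- function(params, histology, dwell) {
  cv <- params$detection$curves[[histology]]
  cv$pmax - (cv$pmax - cv$p0) * exp(-cv$rate * dwell)
}

#' Per-check probability of detecting an undiagnosed melanoma
#'
#' Product of a histology-specific dwell curve (rising for superficial
#' spreading and lentigo maligna, flat for nodular), a body-site
#' visibility factor, a calendar-period technology scaling, and — for
#' organised screening — the test sensitivity. The product is capped at 1.
#'
#' @param histology Histology code.
#' @param dwell Dwell time in years (>= 0).
#' @param calendar_year Calendar year of the check.
#' @param body_site_visible Logical; is the site in the visible class?
#' @param context List with at least `channel`, one of
#'   `"opportunistic_visit"`, `"routine_check"`, `"organised_screen"`,
#'   `"surveillance"`; for `organised_screen` also `sensitivity`.
#' @param params A `mel_parameters` object.
#' @return Probability in \[0,1\].
#' @export
detection_probability <- function(histology, dwell, calendar_year,
                                  body_site_visible, context, params) {
  if (any(dwell < 0)) stop("dwell must be >= 0")
  p <- .detection_curve(params, histology, dwell)
  vis <- ifelse(body_site_visible, 1, params$detection$visibility_less_factor)
  per <- .calendar_ramp(calendar_year, params$detection$period)
  sens <- if (identical(context$channel, "organised_screen")) {
    if (is.null(context$sensitivity)) 1 else context$sensitivity
  } else 1
  pmin(pmax(p * vis * per * sens, 0), 1)
}

# Per-channel specificity (organised rounds use the policy's own value).
.channel_specificity <- function(params, context) {
  if (identical(context$channel, "organised_screen")) {
    if (is.null(context$specificity)) 1 else context$specificity
  } else {
    sp <- params$detection$specificity
    key <- switch(context$channel,
                  opportunistic_visit = "opportunistic_visit",
                  routine_check = "routine_check",
                  surveillance = "surveillance",
                  stop("unknown detection channel: ", context$channel))
    sp[[key]]
  }
}

#' Resolve one attended skin check
#'
#' Reference per-event detection logic: if the individual carries an
#' undiagnosed tumour, it is diagnosed with [detection_probability()]
#' (fixing dwell, stage, Breslow category and behaviour code); if no
#' tumour is present a false positive occurs with probability
#' `1 - specificity`; otherwise nothing happens. Channel gating is
#' enforced: organised screening and routine checks only before the first
#' diagnosis, surveillance only after.
#'
#' @param state List with `age`, `birth_year`, `has_diagnosis` (logical),
#'   and `tumour` (`NULL`, or a list with `histology`, `emergence_age`,
#'   `body_site_visible`).
#' @param context Detection context: `channel`, plus `sensitivity` /
#'   `specificity` for organised rounds.
#' @param stream A `mel_stream` (channel `detection`), or `NULL` with `u`.
#' @param params A `mel_parameters` object.
#' @param u Optional uniform deviate.
#' @return List with `outcome` (`"diagnosis"`, `"false_positive"`, or
#'   `"none"`) and, for a diagnosis, the staging fields.
#' @export
run_check_event <- function(state, context, stream = NULL, params,
                            u = NULL) {
  if (context$channel %in% c("organised_screen", "routine_check") &&
      isTRUE(state$has_diagnosis))
    stop("screening/routine channels are only available before the first ",
         "melanoma diagnosis")
  if (identical(context$channel, "surveillance") &&
      !isTRUE(state$has_diagnosis))
    stop("surveillance only occurs after a first diagnosis")
  if (is.null(u)) u <- stream_uniform(stream, "detection", 1L)
  year <- state$birth_year + state$age
  tum <- state$tumour
  if (!is.null(tum)) {
    dwell <- state$age - tum$emergence_age
    p <- detection_probability(tum$histology, dwell, year,
                               tum$body_site_visible, context, params)
    if (u < p) {
      stg <- stage_at_diagnosis(tum$histology, dwell, params)
      return(c(list(outcome = "diagnosis", diagnosis_age = state$age,
                    dwell_at_diagnosis = dwell), stg))
    }
    return(list(outcome = "none"))
  }
  spec <- .channel_specificity(params, context)
  if (u < 1 - spec) return(list(outcome = "false_positive"))
  list(outcome = "none")
}

#' Surveillance schedule after a first diagnosis
#'
#' Offsets (years from the first diagnosis) of scheduled surveillance
#' skin checks up to the age cap: six-monthly for higher stage or
#' high-risk individuals, annual otherwise. Attendance at each visit is
#' thinned by a decay in time since diagnosis, modulated by stage and
#' histology.
#'
#' @param stage_at_first_diagnosis Stage label at first diagnosis.
#' @param risk_group Risk-group label or list.
#' @param params A `mel_parameters` object.
#' @param diagnosis_age Age at first diagnosis (offsets run to the cap).
#' @return Numeric vector of offsets (years), starting at the first
#'   interval.
#' @export
surveillance_schedule <- function(stage_at_first_diagnosis, risk_group,
                                  params,
                                  diagnosis_age = params$simulation$entry_age) {
  su <- params$surveillance
  lbl <- if (is.character(risk_group)) risk_group else risk_group$label
  intensive <- stage_at_first_diagnosis %in% su$intensive_stages ||
    lbl %in% su$intensive_risk_labels
  step <- if (intensive) su$intensive_interval else su$standard_interval
  horizon <- params$simulation$max_age - diagnosis_age
  if (horizon < step) return(numeric(0))
  seq(step, horizon, by = step)
}

# Surveillance attendance probability at time t since first diagnosis.
.surveillance_attendance <- function(t, stage1, histology1, params) {
  su <- params$surveillance
  p <- su$attendance_initial * exp(-su$attendance_decay * t) *
    su$stage_attendance_factor[[stage1]] *
    su$histology_attendance_factor[[histology1]]
  pmin(pmax(p, 0), 1)
}

# Organised-round calendar times mapped to ages for one individual.
.organised_round_ages <- function(policy, birth_year, params) {
  if (is.null(policy)) return(numeric(0))
  ea <- params$simulation$entry_age
  ma <- params$simulation$max_age
  lo <- max(policy$age_range[1], ea, policy$start_year - birth_year)
  hi <- min(policy$age_range[2], ma)
  if (hi <= lo) return(numeric(0))
  # rounds run on programme calendar years start_year, +interval, ...
  k0 <- max(ceiling((birth_year + lo - policy$start_year) /
                      policy$interval), 0)
  nk <- floor((birth_year + hi - policy$start_year) / policy$interval) - k0
  if (nk < 0) return(numeric(0))
  yrs <- policy$start_year + (k0 + 0:nk) * policy$interval
  ages <- yrs - birth_year
  ages[ages >= lo & ages <= hi]
}
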