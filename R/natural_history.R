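# Natural history: emergence hazards for first and subsequent primary
# melanomas, histology and body-site assignment, and implicit progression
# (stage and Breslow category as a pure function of histology and dwell
# time). There are no explicit states for an undiagnosed tumour.

#' Birth-cohort effect on melanoma emergence
#'
#' Piecewise multiplier on the baseline emergence hazard: the reference
#' plateau (1.0) for birth years up to the decline start (1972 by
#' default), a linear monotone decline until the decline end (1992),
#' and a constant floor afterwards — reflecting lower lifetime UV
#' exposure in cohorts born after sun-protection campaigns began.
#'
#' @param birth_year Real-valued birth year (vectorised).
#' @param params A `mel_parameters` object.
#' @return Positive multiplier(s).
#' @export
cohort_effect <- function(birth_year, params) {
  ce <- params$cohort_effect
  f <- pmin(pmax((birth_year - ce$decline_start) /
                   max(ce$decline_end - ce$decline_start, 1e-12), 0), 1)
  1 - f * (1 - ce$floor)
}

# Baseline incidence step rates for one sex, scaled.
.baseline_rates <- function(params, sex) {
  bi <- params$baseline_incidence
  sc <- if (is.null(bi$scale)) 1 else bi$scale
  r <- if (sex == "female") bi$female else bi$male
  r * sc
}

#' First-primary melanoma emergence hazard
#'
#' `baseline_incidence(age, sex) * cohort_effect(birth_year) *
#' relative_risk`: the well-to-undiagnosed transition rate. Individual
#' risk scales the whole age profile without changing its shape.
#'
#' @param age Age(s) in years, at or above the entry age.
#' @param sex `"male"` or `"female"`.
#' @param birth_year Real birth year.
#' @param risk_group Risk-group label (e.g. `"average"`) or a risk-group
#'   list with a `relative_risk` field.
#' @param params A `mel_parameters` object.
#' @return Rate(s) per person-year.
#' @export
first_primary_hazard <- function(age, sex, birth_year, risk_group, params) {
  if (any(age < params$simulation$entry_age))
    stop("age below entry age")
  rg <- if (is.character(risk_group)) .risk_group(params, risk_group)
        else risk_group
  haz <- .first_primary_pc(params, sex, birth_year, rg)
  pc_rate(haz, age)
}

# The same hazard as a pc_hazard object (used by the engine for inversion
# sampling). Scalar multipliers keep it piecewise-constant in age.
.first_primary_pc <- function(params, sex, birth_year, rg) {
  bi <- params$baseline_incidence
  mult <- cohort_effect(birth_year, params) * rg$relative_risk
  pc_hazard(bi$age_breaks, .baseline_rates(params, sex) * mult)
}

.subsequent_pc <- function(params, sex, birth_year, rg, first_histology,
                           n_previous) {
  base <- .first_primary_pc(params, sex, birth_year, rg)
  m <- post_diagnosis_risk_multiplier(n_previous, params) *
    params$subsequent_histology_factor[[first_histology]]
  pc_hazard(base$breaks, base$rates * m)
}

#' Post-diagnosis risk multiplier
#'
#' Multiplier (> 1, non-decreasing) applied to the emergence hazard after
#' `n_previous` diagnosed primaries; beyond the configured sequence the
#' last value is carried forward.
#'
#' @param n_previous Number of previously diagnosed primaries (>= 1).
#' @param params A `mel_parameters` object.
#' @return Multiplier > 1.
#' @export
post_diagnosis_risk_multiplier <- function(n_previous, params) {
  if (any(n_previous < 1)) stop("n_previous must be >= 1")
  pm <- params$post_diagnosis_risk_multipliers
  pm[pmin(as.integer(n_previous), length(pm))]
}

#' Subsequent-primary melanoma emergence hazard
#'
#' The first-primary-style hazard scaled by the post-diagnosis risk
#' multiplier and a histology-specific factor for the first primary's
#' subtype. Progression of the new tumour uses the same stage schedules
#' as a first tumour of its histology.
#'
#' @inheritParams first_primary_hazard
#' @param first_histology Histology code of the first primary.
#' @param n_previous Number of previously diagnosed primaries (>= 1).
#' @return Rate(s) per person-year.
#' @export
subsequent_primary_hazard <- function(age, sex, birth_year, risk_group,
                                      first_histology, n_previous, params) {
  if (any(age < params$simulation$entry_age)) stop("age below entry age")
  rg <- if (is.character(risk_group)) .risk_group(params, risk_group)
        else risk_group
  haz <- .subsequent_pc(params, sex, birth_year, rg, first_histology,
                        n_previous)
  pc_rate(haz, age)
}

# Age-band histology proportions.
.histology_props <- function(params, age) {
  hm <- params$histology_mix
  i <- findInterval(age, hm$age_breaks, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(hm$props))
  hm$props[[i]]
}

#' Assign a histological subtype at emergence
#'
#' Draws one of the four subtypes from the age-indexed mix. The mix is
#' identical for both sexes (the operation takes no sex argument) and has
#' no calendar-time dependence.
#'
#' @param age Age at emergence.
#' @param stream A `mel_stream` (channel `tumour_attr` is consumed), or
#'   `NULL` when `u` is supplied.
#' @param params A `mel_parameters` object.
#' @param u Optional uniform deviate.
#' @return Histology code.
#' @export
assign_histology <- function(age, stream, params, u = NULL) {
  if (is.null(u)) u <- stream_uniform(stream, "tumour_attr", 1L)
  p <- .histology_props(params, age)
  .mel_histologies[findInterval(u, cumsum(p)) + 1L]
}

#' Assign the histology of a subsequent primary
#'
#' With probability equal to the configured concordance the new primary
#' shares the first primary's subtype; the remaining mass is split among
#' the other subtypes in proportion to the marginal mix at the current
#' age.
#'
#' @param first_histology Histology code of the first primary.
#' @param age Age at emergence of the new tumour.
#' @param stream A `mel_stream` (channel `tumour_attr`), or `NULL`.
#' @param params A `mel_parameters` object.
#' @param u Optional vector of one or two uniform deviates.
#' @return Histology code.
#' @export
assign_subsequent_histology <- function(first_histology, age, stream,
                                        params, u = NULL) {
  if (is.null(u)) u <- stream_uniform(stream, "tumour_attr", 2L)
  conc <- params$subsequent_histology_concordance
  if (u[1L] < conc) return(first_histology)
  p <- .histology_props(params, age)
  keep <- .mel_histologies != first_histology
  p <- p[keep] / sum(p[keep])
  .mel_histologies[keep][findInterval(u[2L], cumsum(p)) + 1L]
}

# Body site drawn once at emergence from the configured categorical
# distribution over ICD-O-3 topography codes C44.0-C44.9.
.assign_body_site <- function(stream, params, u = NULL) {
  if (is.null(u)) u <- stream_uniform(stream, "tumour_attr", 1L)
  bs <- params$body_sites
  i <- findInterval(u, cumsum(bs$probs)) + 1L
  i <- min(i, length(bs$codes))
  list(code = bs$codes[i], visible = bs$visible[i])
}

#' Stage, Breslow category and behaviour code at diagnosis
#'
#' Implicit progression: the stage at diagnosis is a pure function of the
#' tumour's histology and its dwell (sojourn) time — the longer a tumour
#' stays undiagnosed, the later the stage. Dwell 0 maps to in situ.
#' Within stages I-II the dwell cutpoints map to a Breslow thickness
#' category; the behaviour code is 2 for in situ and 3 for invasive
#' disease.
#'
#' @param histology Histology code.
#' @param dwell Dwell time in years (>= 0).
#' @param params A `mel_parameters` object.
#' @return List with `stage`, `breslow_category` (`NA` outside stages
#'   I-II) and `behaviour_code`.
#' @export
stage_at_diagnosis <- function(histology, dwell, params) {
  if (dwell < 0) stop("dwell must be >= 0")
  sch <- params$stage_schedules[[histology]]
  if (is.null(sch)) stop("unknown histology: ", histology)
  th <- unlist(sch$thresholds[c("I", "II", "III", "IV")])
  stage <- .mel_stages[findInterval(dwell, th) + 1L]
  breslow <- NA_character_
  if (stage %in% c("I", "II")) {
    bc <- sch$breslow_cutpoints
    breslow <- .mel_breslow[findInterval(dwell, bc) + 1L]
  }
  list(stage = stage,
       breslow_category = breslow,
       behaviour_code = if (stage == "in_situ") 2L else 3L)
}

# ICD-O-3 morphology band labels by histology (M872-M879 family).
.mel_morphology <- c(superficial_spreading = "M8743",
                     lentigo_maligna = "M8742",
                     nodular = "M8721",
                     other = "M8720")
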