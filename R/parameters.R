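# Parameter set: every rate, probability, schedule and tariff the simulator
# consumes. Stored as nested lists of plain vectors so the YAML round trip is
# faithful. All times are in years, rates per person-year, currency in AUD.

.mel_histologies <- c("superficial_spreading", "lentigo_maligna",
                      "nodular", "other")
.mel_stages <- c("in_situ", "I", "II", "III", "IV")
.mel_breslow <- c("le_1mm", "b1_4mm", "gt_4mm")
.mel_schema_version <- 1L

#' Packaged Australian-like default parameter set
#'
#' Returns the synthetic default fixture: an Australian-like age/sex/birth-
#' cohort incidence pattern, three risk groups (low/average/high), a
#' histology mix that shifts towards lentigo maligna with age,
#' histology-specific stage schedules (nodular reaches stage IV after a
#' 0.5-year dwell, lentigo maligna after 20 years), detection curves,
#' surveillance rules, stage/thickness survival profiles, an other-cause
#' life table, and the economics block (5% annual discounting, AUD 50,000
#' per QALY willingness-to-pay). The subsequent-primary risk multipliers
#' were fixed by calibrating the simulated 10-year second-primary
#' proportion to the national figure of about 16%.
#'
#' @return A validated object of class `mel_parameters`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$simulation$entry_age
default_parameters <- function() {
  params <- list(
    schema_version = .mel_schema_version,
    simulation = list(entry_age = 15, max_age = 85),
    demographics = list(prop_female = 0.5,
                        birth_year_min = 1935, birth_year_max = 1995),
    baseline_incidence = list(
      # piecewise-constant over 5-year age bands, per person-year
      age_breaks = seq(15, 85, by = 5),
      male = c(10, 15, 25, 40, 60, 90, 130, 180,
               240, 300, 360, 420, 470, 500) / 1e5,
      female = c(15, 20, 30, 45, 60, 75, 90, 110,
                 130, 150, 170, 190, 210, 230) / 1e5,
      scale = 1.0
    ),
    cohort_effect = list(decline_start = 1972, decline_end = 1992,
                         floor = 0.65),
    risk_groups = list(
      list(label = "low", fraction = 0.25, relative_risk = 0.5,
           uptake_multiplier = 0.7),
      list(label = "average", fraction = 0.55, relative_risk = 1.0,
           uptake_multiplier = 1.0),
      list(label = "high", fraction = 0.20, relative_risk = 2.75,
           uptake_multiplier = 1.4)
    ),
    histology_mix = list(
      age_breaks = c(15, 40, 60, 85),
      codes = .mel_histologies,
      props = list(
        c(0.62, 0.03, 0.10, 0.25),
        c(0.55, 0.10, 0.12, 0.23),
        c(0.42, 0.22, 0.14, 0.22)
      )
    ),
    stage_schedules = list(
      superficial_spreading = list(
        thresholds = list(I = 1.0, II = 3.0, III = 5.0, IV = 7.0),
        breslow_cutpoints = c(1.8, 4.0)),
      lentigo_maligna = list(
        thresholds = list(I = 8.0, II = 14.0, III = 18.0, IV = 20.0),
        breslow_cutpoints = c(10.0, 16.0)),
      nodular = list(
        thresholds = list(I = 0.1, II = 0.25, III = 0.4, IV = 0.5),
        breslow_cutpoints = c(0.15, 0.3)),
      other = list(
        thresholds = list(I = 1.5, II = 4.0, III = 6.5, IV = 9.0),
        breslow_cutpoints = c(2.5, 5.5))
    ),
    body_sites = list(
      codes = paste0("C44.", 0:9),
      probs = c(0.02, 0.03, 0.08, 0.12, 0.05, 0.25, 0.20, 0.18, 0.04, 0.03),
      visible = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                  FALSE, FALSE)
    ),
    detection = list(
      # per-check detection probability: p(dwell) = pmax - (pmax-p0) e^{-r d}
      curves = list(
        superficial_spreading = list(p0 = 0.25, pmax = 0.80, rate = 0.8),
        lentigo_maligna = list(p0 = 0.12, pmax = 0.65, rate = 0.15),
        nodular = list(p0 = 0.35, pmax = 0.35, rate = 0.0),
        other = list(p0 = 0.20, pmax = 0.70, rate = 0.5)
      ),
      visibility_less_factor = 0.8,
      period = list(start_year = 1980, end_year = 2010,
                    start_factor = 0.7, end_factor = 1.0),
      specificity = list(opportunistic_visit = 0.99, routine_check = 0.985,
                         surveillance = 0.985)
    ),
    uptake_model = list(
      age_breaks = c(15, 30, 45, 60, 85),
      rates = c(0.005, 0.02, 0.04, 0.05),
      female_factor = 1.2,
      calendar = list(start_year = 1980, end_year = 2015,
                      start_factor = 0.15, end_factor = 1.0)
    ),
    attendance = list(initial = 0.9, decay_rate = 0.05),
    routine_interval = 1.0,
    visit_rates = list(
      age_breaks = c(15, 30, 45, 60, 85),
      rates = c(0.12, 0.15, 0.20, 0.30),
      female_factor = 1.15,
      # symptom-prompted presentation: up to (1 + emergence_boost) times
      # the background rate as the tumour approaches full progression
      emergence_boost = 2,
      boost_cap_years = 5
    ),
    # fixed by a 1-D calibration of the simulated 10-year second-primary
    # proportion to the ~16% national figure
    post_diagnosis_risk_multipliers = c(6.0, 7.5, 9.0, 10.5),
    subsequent_histology_concordance = 0.55,
    subsequent_histology_factor = list(
      superficial_spreading = 1.0, lentigo_maligna = 1.0,
      nodular = 1.0, other = 1.0),
    survival = list(
      time_breaks = c(0, 1, 5),
      # melanoma-specific death hazard (per year) by stage, Breslow
      # category within stages I-II, and time-since-diagnosis band
      hazards = list(
        in_situ = list(any = c(0, 0, 0)),
        I = list(le_1mm = c(0.001, 0.002, 0.001),
                 b1_4mm = c(0.010, 0.012, 0.006),
                 gt_4mm = c(0.020, 0.020, 0.010)),
        II = list(le_1mm = c(0.015, 0.020, 0.010),
                  b1_4mm = c(0.030, 0.035, 0.015),
                  gt_4mm = c(0.050, 0.050, 0.020)),
        III = list(any = c(0.080, 0.090, 0.040)),
        IV = list(any = c(0.50, 0.35, 0.12))
      )
    ),
    surveillance = list(
      intensive_interval = 0.5,
      standard_interval = 1.0,
      intensive_stages = c("III", "IV"),
      intensive_risk_labels = "high",
      attendance_initial = 0.95,
      attendance_decay = 0.04,
      stage_attendance_factor = list(in_situ = 0.95, I = 1.0, II = 1.0,
                                     III = 1.0, IV = 1.0),
      histology_attendance_factor = list(
        superficial_spreading = 1.0, lentigo_maligna = 1.0,
        nodular = 1.0, other = 1.0)
    ),
    economics = list(
      discount_rate = 0.05,
      wtp_threshold = 50000,
      keratinocyte_adjunct_cost = 15,
      tariff = list(
        check_cost = list(opportunistic_visit = 40, routine_check = 45,
                          organised_screen = 60, surveillance = 80),
        diagnostic_excision = 320,
        false_positive_workup = 180,
        treatment_initial = list(in_situ = 600, I = 1800, II = 4500,
                                 III = 32000, IV = 110000),
        treatment_continuing = list(in_situ = 0, I = 120, II = 350,
                                    III = 2500, IV = 18000),
        continuing_years = 5,
        program_per_invitee = 5,
        program_fixed_annual = 0
      ),
      utilities = list(well = 1.0, in_situ = 0.97, I = 0.95, II = 0.92,
                       III = 0.85, IV = 0.70)
    ),
    life_table = list(
      age_breaks = seq(15, 85, by = 5),
      male = c(0.0005, 0.0008, 0.0009, 0.0010, 0.0013, 0.0018, 0.0025,
               0.0040, 0.0060, 0.0090, 0.0140, 0.0220, 0.0360, 0.0600),
      female = c(0.0003, 0.0004, 0.0005, 0.0006, 0.0009, 0.0013, 0.0019,
                 0.0030, 0.0045, 0.0070, 0.0110, 0.0170, 0.0280, 0.0480)
    )
  )
  class(params) <- c("mel_parameters", "list")
  params
}

# ---- dotted-path access ------------------------------------------------

#' Get or set a parameter by dotted path
#'
#' Paths address nested list entries by name or 1-based index, e.g.
#' `"baseline_incidence.scale"` or `"post_diagnosis_risk_multipliers.1"`.
#'
#' @param params A `mel_parameters` object.
#' @param path Dotted path string.
#' @param value Replacement value (for `param_set`).
#' @return `param_get` returns the addressed value; `param_set` the
#'   modified parameter set.
#' @export
param_get <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- params
  for (p in parts) {
    idx <- suppressWarnings(as.integer(p))
    node <- if (!is.na(idx)) node[[idx]] else node[[p]]
    if (is.null(node)) stop("unknown parameter path: ", path)
  }
  node
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  rec <- function(node, parts) {
    p <- parts[1L]
    idx <- suppressWarnings(as.integer(p))
    key <- if (!is.na(idx)) idx else p
    if (is.null(if (!is.na(idx)) node[[idx]] else node[[p]]))
      stop("unknown parameter path: ", path)
    if (length(parts) == 1L) node[[key]] <- value
    else node[[key]] <- rec(node[[key]], parts[-1L])
    node
  }
  out <- rec(unclass(params), parts)
  class(out) <- c("mel_parameters", "list")
  out
}

# ---- validation --------------------------------------------------------

.vreport <- function() data.frame(path = character(), message = character(),
                                  stringsAsFactors = FALSE)
.vadd <- function(rep, path, msg) {
  rbind(rep, data.frame(path = path, message = msg, stringsAsFactors = FALSE))
}

#' Validate a parameter set
#'
#' Checks every structural invariant (non-negative hazards, probabilities
#' in \[0,1\], risk-group fractions summing to one with exactly one
#' reference group, strictly increasing stage-schedule thresholds,
#' histology proportions summing to one, entry age below the age cap, ...)
#' and reports each breach with its parameter path. An empty report means
#' the set is valid.
#'
#' @param params A `mel_parameters` object.
#' @return A data frame with columns `path` and `message`; zero rows iff
#'   valid.
#' @export
validate_parameters <- function(params) {
  rep <- .vreport()
  sim <- params$simulation
  if (is.null(sim) || !is.numeric(sim$entry_age) || !is.numeric(sim$max_age))
    return(.vadd(rep, "simulation", "entry_age/max_age missing"))
  if (sim$entry_age >= sim$max_age)
    rep <- .vadd(rep, "simulation", "entry_age must be < max_age")

  dem <- params$demographics
  if (dem$prop_female < 0 || dem$prop_female > 1)
    rep <- .vadd(rep, "demographics.prop_female", "must be in [0,1]")

  bi <- params$baseline_incidence
  if (any(bi$male < 0) || any(bi$female < 0))
    rep <- .vadd(rep, "baseline_incidence", "hazards must be >= 0")
  if (length(bi$male) != length(bi$age_breaks) - 1L ||
      length(bi$female) != length(bi$age_breaks) - 1L)
    rep <- .vadd(rep, "baseline_incidence", "rate/break length mismatch")
  if (!is.null(bi$scale) && bi$scale < 0)
    rep <- .vadd(rep, "baseline_incidence.scale", "must be >= 0")

  ce <- params$cohort_effect
  if (ce$decline_start > ce$decline_end)
    rep <- .vadd(rep, "cohort_effect", "decline_start must be <= decline_end")
  if (ce$floor <= 0 || ce$floor > 1)
    rep <- .vadd(rep, "cohort_effect.floor", "must be in (0,1]")

  rg <- params$risk_groups
  fr <- vapply(rg, `[[`, numeric(1), "fraction")
  rr <- vapply(rg, `[[`, numeric(1), "relative_risk")
  um <- vapply(rg, `[[`, numeric(1), "uptake_multiplier")
  if (abs(sum(fr) - 1) > 1e-9)
    rep <- .vadd(rep, "risk_groups", "fractions must sum to 1")
  if (any(rr <= 0))
    rep <- .vadd(rep, "risk_groups", "relative_risk must be > 0")
  if (any(um < 0))
    rep <- .vadd(rep, "risk_groups", "uptake_multiplier must be >= 0")
  if (sum(abs(rr - 1) < 1e-12) != 1L)
    rep <- .vadd(rep, "risk_groups",
                 "exactly one group must have relative_risk = 1 (reference)")

  hm <- params$histology_mix
  if (!identical(as.character(hm$codes), .mel_histologies))
    rep <- .vadd(rep, "histology_mix.codes",
                 "must be the four histology codes in canonical order")
  if (length(hm$props) != length(hm$age_breaks) - 1L)
    rep <- .vadd(rep, "histology_mix", "props/age_breaks length mismatch")
  for (i in seq_along(hm$props)) {
    p <- hm$props[[i]]
    if (length(p) != length(hm$codes) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9)
      rep <- .vadd(rep, sprintf("histology_mix.props.%d", i),
                   "proportions must be non-negative and sum to 1")
  }

  for (h in .mel_histologies) {
    sch <- params$stage_schedules[[h]]
    if (is.null(sch)) {
      rep <- .vadd(rep, paste0("stage_schedules.", h), "missing schedule")
      next
    }
    th <- unlist(sch$thresholds[c("I", "II", "III", "IV")])
    if (length(th) != 4L || any(is.na(th)) || any(diff(th) <= 0) ||
        th[1] <= 0)
      rep <- .vadd(rep, paste0("stage_schedules.", h),
                   "thresholds must be positive and strictly increasing")
    bc <- sch$breslow_cutpoints
    if (length(bc) != 2L || any(diff(bc) <= 0))
      rep <- .vadd(rep, paste0("stage_schedules.", h, ".breslow_cutpoints"),
                   "need two strictly increasing dwell cutpoints")
  }

  bs <- params$body_sites
  if (abs(sum(bs$probs) - 1) > 1e-9 || any(bs$probs < 0))
    rep <- .vadd(rep, "body_sites.probs",
                 "must be non-negative and sum to 1")

  det <- params$detection
  for (h in .mel_histologies) {
    cv <- det$curves[[h]]
    bad <- is.null(cv) || cv$p0 < 0 || cv$p0 > 1 || cv$pmax < 0 ||
      cv$pmax > 1 || cv$pmax < cv$p0 || cv$rate < 0
    if (bad)
      rep <- .vadd(rep, paste0("detection.curves.", h),
                   "need 0 <= p0 <= pmax <= 1 and rate >= 0")
  }
  if (det$visibility_less_factor < 0 || det$visibility_less_factor > 1)
    rep <- .vadd(rep, "detection.visibility_less_factor", "must be in [0,1]")
  pr <- det$period
  if (pr$start_factor <= 0 || pr$end_factor <= 0 ||
      pr$start_year > pr$end_year)
    rep <- .vadd(rep, "detection.period", "invalid period scaling block")
  for (nm in names(det$specificity))
    if (det$specificity[[nm]] < 0 || det$specificity[[nm]] > 1)
      rep <- .vadd(rep, paste0("detection.specificity.", nm),
                   "must be in [0,1]")

  up <- params$uptake_model
  if (any(up$rates < 0) || length(up$rates) != length(up$age_breaks) - 1L)
    rep <- .vadd(rep, "uptake_model", "rates must be >= 0 and match breaks")
  att <- params$attendance
  if (att$initial < 0 || att$initial > 1 || att$decay_rate < 0)
    rep <- .vadd(rep, "attendance", "initial in [0,1], decay_rate >= 0")
  if (params$routine_interval <= 0)
    rep <- .vadd(rep, "routine_interval", "must be > 0")
  vr <- params$visit_rates
  if (any(vr$rates < 0) || length(vr$rates) != length(vr$age_breaks) - 1L)
    rep <- .vadd(rep, "visit_rates", "rates must be >= 0 and match breaks")
  if (vr$emergence_boost < 0 || vr$boost_cap_years < 0)
    rep <- .vadd(rep, "visit_rates", "boost parameters must be >= 0")

  pm <- params$post_diagnosis_risk_multipliers
  if (any(pm <= 1))
    rep <- .vadd(rep, "post_diagnosis_risk_multipliers", "must all be > 1")
  if (any(diff(pm) < 0))
    rep <- .vadd(rep, "post_diagnosis_risk_multipliers",
                 "must be non-decreasing")
  conc <- params$subsequent_histology_concordance
  if (conc < 0 || conc > 1)
    rep <- .vadd(rep, "subsequent_histology_concordance", "must be in [0,1]")

  sv <- params$survival
  if (length(sv$time_breaks) != 3L || any(diff(sv$time_breaks) <= 0))
    rep <- .vadd(rep, "survival.time_breaks",
                 "need three increasing band starts")
  for (st in names(sv$hazards))
    for (b in names(sv$hazards[[st]]))
      if (any(sv$hazards[[st]][[b]] < 0))
        rep <- .vadd(rep, sprintf("survival.hazards.%s.%s", st, b),
                     "hazards must be >= 0")

  su <- params$surveillance
  if (su$intensive_interval <= 0 || su$standard_interval <= 0 ||
      su$intensive_interval > su$standard_interval)
    rep <- .vadd(rep, "surveillance",
                 "need 0 < intensive_interval <= standard_interval")
  if (su$attendance_initial < 0 || su$attendance_initial > 1 ||
      su$attendance_decay < 0)
    rep <- .vadd(rep, "surveillance", "attendance block out of range")

  ec <- params$economics
  if (ec$discount_rate < 0)
    rep <- .vadd(rep, "economics.discount_rate", "must be >= 0")
  if (ec$wtp_threshold < 0)
    rep <- .vadd(rep, "economics.wtp_threshold", "must be >= 0")
  costs <- c(unlist(ec$tariff$check_cost), ec$tariff$diagnostic_excision,
             ec$tariff$false_positive_workup,
             unlist(ec$tariff$treatment_initial),
             unlist(ec$tariff$treatment_continuing),
             ec$tariff$program_per_invitee, ec$tariff$program_fixed_annual,
             ec$keratinocyte_adjunct_cost)
  if (any(costs < 0))
    rep <- .vadd(rep, "economics.tariff", "costs must be >= 0")
  utl <- unlist(ec$utilities)
  if (any(utl < 0) || any(utl > 1))
    rep <- .vadd(rep, "economics.utilities", "weights must be in [0,1]")
  if (any(utl[setdiff(names(utl), "well")] > ec$utilities$well))
    rep <- .vadd(rep, "economics.utilities",
                 "well-state weight must be >= post-diagnosis weights")

  lt <- params$life_table
  if (any(lt$male < 0) || any(lt$female < 0))
    rep <- .vadd(rep, "life_table", "rates must be >= 0")
  if (length(lt$male) != length(lt$age_breaks) - 1L ||
      length(lt$female) != length(lt$age_breaks) - 1L)
    rep <- .vadd(rep, "life_table", "rate/break length mismatch")
  if (abs(lt$age_breaks[1] - sim$entry_age) > 1e-9 ||
      lt$age_breaks[length(lt$age_breaks)] < sim$max_age)
    rep <- .vadd(rep, "life_table.age_breaks",
                 "bands must cover [entry_age, max_age]")
  rep
}

# ---- serialisation -----------------------------------------------------

# Recursively compare key structure against the default skeleton so unknown
# keys are rejected on load.
.check_keys <- function(node, ref, path = "") {
  if (!is.list(node) || !is.list(ref)) return(character(0))
  if (is.null(names(ref)) || any(names(ref) == "")) return(character(0))
  bad <- setdiff(names(node), names(ref))
  out <- if (length(bad)) paste0(path, bad) else character(0)
  for (nm in intersect(names(node), names(ref)))
    out <- c(out, .check_keys(node[[nm]], ref[[nm]], paste0(path, nm, ".")))
  out
}

#' Load a parameter set from a YAML document
#'
#' Reads a versioned YAML configuration, rejects unknown keys and schema
#' versions, fills nothing in silently, and validates every invariant.
#'
#' @param source Path to a YAML file written by [write_parameters()] (or
#'   hand-authored to the same schema).
#' @return A validated `mel_parameters` object.
#' @export
load_parameters <- function(source) {
  raw <- yaml::read_yaml(source)
  if (is.null(raw$schema_version) ||
      raw$schema_version != .mel_schema_version)
    stop("unsupported or missing schema_version (expected ",
         .mel_schema_version, ")")
  unknown <- .check_keys(raw, unclass(default_parameters()))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  params <- raw
  class(params) <- c("mel_parameters", "list")
  rep <- validate_parameters(params)
  if (nrow(rep))
    stop("invalid parameter set:\n",
         paste0("  ", rep$path, ": ", rep$message, collapse = "\n"))
  params
}

#' Write a parameter set to YAML
#'
#' @param params A `mel_parameters` object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' @export
print.mel_parameters <- function(x, ...) {
  cat("<mel_parameters> schema", x$schema_version,
      "| entry", x$simulation$entry_age, "- cap", x$simulation$max_age,
      "|", length(x$risk_groups), "risk groups\n")
  invisible(x)
}

# Internal lookups used across modules.
.risk_group <- function(params, label) {
  for (g in params$risk_groups) if (g$label == label) return(g)
  stop("unknown risk group: ", label)
}
.risk_labels <- function(params)
  vapply(params$risk_groups, `[[`, character(1), "label")
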