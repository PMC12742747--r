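# Shared test fixtures, all built in code.

# cache for expensive cohorts shared across test files
.mel_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .mel_test_cache)) assign(key, force(expr),
                                            .mel_test_cache)
  get(key, .mel_test_cache)
}

# Default 10^4 cohort with events, shared by structural/gating checks.
shared_cohort_10k <- function() cached("c10k", {
  simulate_cohort(default_parameters(), 1e4, 20260915)
})

# Large event-free cohort for the epidemiological anchor and survival
# ordering.
shared_cohort_100k <- function() cached("c100k", {
  simulate_cohort(default_parameters(), 1e5, 20260915,
                  keep_events = FALSE)
})

# Screened cohort (organised annual programme) for length-time checks.
shared_screened_40k <- function() cached("s40k", {
  simulate_cohort(default_parameters(), 4e4, 31,
                  policy = screening_policy(interval = 1),
                  keep_events = FALSE)
})

# Single-risk-group parameter set with flat constant hazards: melanoma
# emergence lambda_mel, other-cause lambda_oc, optionally no detection at
# all (visits/uptake zeroed).
flat_params <- function(lambda_mel = 0, lambda_oc = 0,
                        visits = 0, uptake = 0, cohort_floor = 1) {
  p <- default_parameters()
  nb <- length(p$baseline_incidence$male)
  p$baseline_incidence$male <- rep(lambda_mel, nb)
  p$baseline_incidence$female <- rep(lambda_mel, nb)
  p$cohort_effect$floor <- cohort_floor
  p$risk_groups <- list(list(label = "average", fraction = 1,
                             relative_risk = 1, uptake_multiplier = 1))
  p$life_table$male <- rep(lambda_oc, length(p$life_table$male))
  p$life_table$female <- rep(lambda_oc, length(p$life_table$female))
  p$visit_rates$rates <- rep(visits, length(p$visit_rates$rates))
  p$visit_rates$female_factor <- 1
  p$uptake_model$rates <- rep(uptake, length(p$uptake_model$rates))
  p
}

# Hand-buildable life history for accrual toys.
toy_history <- function(events, tumours = list(), exit_age = 85,
                        exit_cause = "age_cap", sex = "male",
                        birth_year = 1960) {
  structure(list(id = 1, sex = sex, birth_year = birth_year,
                 events = events, tumours = tumours,
                 n_false_positives = 0,
                 risk_group = "average",
                 exit_age = exit_age, exit_cause = exit_cause),
            class = "mel_history")
}

toy_event_matrix <- function(age, type, channel = 0L, outcome = 0L,
                             tumour = 0L) {
  cbind(age = age, type = type, channel = channel, outcome = outcome,
        tumour = tumour)
}

# Wrap histories into a minimal cohort object.
toy_cohort <- function(histories, seed = 1, entry_age = 15,
                       max_age = 85) {
  for (i in seq_along(histories)) histories[[i]]$id <- i
  structure(list(histories = histories, n = length(histories),
                 seed = seed, policy = NULL, entry_age = entry_age,
                 max_age = max_age), class = "mel_cohort")
}

toy_tumour <- function(index = 1L, histology = "superficial_spreading",
                       emergence_age = 50, diagnosis_age = 52,
                       stage = "I", breslow = "le_1mm",
                       behaviour = 3L, channel = "opportunistic_visit",
                       diagnosed = TRUE) {
  list(tumour_index = index, histology = histology,
       emergence_age = emergence_age, body_site = "C44.5",
       body_site_visible = TRUE, diagnosed = diagnosed,
       diagnosis_age = if (diagnosed) diagnosis_age else NA_real_,
       dwell_at_diagnosis = if (diagnosed) diagnosis_age - emergence_age
                            else NA_real_,
       stage_at_diagnosis = if (diagnosed) stage else NA_character_,
       breslow_category = if (diagnosed) breslow else NA_character_,
       behaviour_code = if (diagnosed) behaviour else NA_integer_,
       detect_channel = if (diagnosed) channel else NA_character_)
}
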