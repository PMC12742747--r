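test_that("uptake hazard: calendar growth, risk scaling, gating", {
  p <- default_parameters()
  expect_gte(uptake_hazard(50, "male", "average", 2020, p),
             uptake_hazard(50, "male", "average", 1990, p))
  expect_gte(uptake_hazard(50, "male", "high", 2020, p),
             uptake_hazard(50, "male", "average", 2020, p))
  rg0 <- list(label = "none", relative_risk = 1, uptake_multiplier = 0)
  expect_identical(uptake_hazard(50, "male", rg0, 2020, p), 0)
  expect_error(uptake_hazard(50, "male", "average", 2020, p,
                             diagnosed = TRUE), "before the first")
})

test_that("routine attendance starts at initial compliance and decays", {
  p <- default_parameters()
  expect_equal(attendance_probability(0, p), p$attendance$initial)
  expect_lte(attendance_probability(5, p), attendance_probability(1, p))
  q <- p
  q$attendance$decay_rate <- 0
  expect_equal(attendance_probability(25, q), q$attendance$initial)
  expect_error(attendance_probability(-1, p), ">= 0")
})

test_that("visit hazard: baseline when well, boosted after emergence", {
  p <- default_parameters()
  base <- visit_hazard(50, "male", "average", NULL, p)
  expect_gt(base, 0)
  expect_identical(visit_hazard(50, "male", "average", NA, p), base)
  expect_gte(visit_hazard(50, "male", "average", 3, p),
             visit_hazard(50, "male", "average", 0.1, p))
})

test_that("detection probability: curves, period cap, channel factors", {
  p <- default_parameters()
  ctx <- list(channel = "opportunistic_visit")
  grid <- seq(0, 25, by = 0.05)
  pss <- detection_probability("superficial_spreading", grid, 2015, TRUE,
                               ctx, p)
  expect_true(all(diff(pss) >= -1e-12))
  pn <- detection_probability("nodular", grid, 2015, TRUE, ctx, p)
  expect_equal(max(pn) - min(pn), 0)
  # period scaling grows and never pushes the product above 1
  expect_gte(detection_probability("superficial_spreading", 2, 2020,
                                   TRUE, ctx, p),
             detection_probability("superficial_spreading", 2, 1985,
                                   TRUE, ctx, p))
  expect_true(all(pss >= 0 & pss <= 1))
  # less-visible body sites reduce detection
  expect_lt(detection_probability("superficial_spreading", 2, 2015,
                                  FALSE, ctx, p),
            detection_probability("superficial_spreading", 2, 2015,
                                  TRUE, ctx, p))
  # organised screening multiplies in the test sensitivity
  ctxs <- list(channel = "organised_screen", sensitivity = 0.5)
  expect_equal(detection_probability("nodular", 1, 2015, TRUE, ctxs, p),
               0.5 * detection_probability("nodular", 1, 2015, TRUE,
                                           ctx, p))
})

test_that("run_check_event: forced detection, specificity, gating", {
  p <- default_parameters()
  state_tum <- list(age = 52, birth_year = 1960, has_diagnosis = FALSE,
                    tumour = list(histology = "superficial_spreading",
                                  emergence_age = 50,
                                  body_site_visible = TRUE))
  ctx <- list(channel = "routine_check")
  # u = 0 forces detection; staging comes from the dwell schedule
  r <- run_check_event(state_tum, ctx, params = p, u = 0)
  expect_identical(r$outcome, "diagnosis")
  expect_equal(r$dwell_at_diagnosis, 2)
  expect_identical(r$stage,
                   stage_at_diagnosis("superficial_spreading", 2, p)$stage)
  # specificity 1: nothing ever happens in melanoma-free skin
  q <- p
  q$detection$specificity$routine_check <- 1
  state_free <- list(age = 52, birth_year = 1960, has_diagnosis = FALSE,
                     tumour = NULL)
  for (u in c(0, 1e-9, 0.5, 0.999))
    expect_identical(run_check_event(state_free, ctx, params = q,
                                     u = u)$outcome, "none")
  # specificity 0.9: ~10% false positives
  q$detection$specificity$routine_check <- 0.9
  set.seed(8)
  n <- 2e4
  fp <- vapply(runif(n), function(u)
    run_check_event(state_free, ctx, params = q,
                    u = u)$outcome == "false_positive", logical(1))
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(fp) - 0.1), 3 * se)
  # channel gating contracts
  state_dx <- list(age = 60, birth_year = 1960, has_diagnosis = TRUE,
                   tumour = NULL)
  expect_error(run_check_event(state_dx, list(channel = "routine_check"),
                               params = p, u = 0.5), "before the first")
  expect_error(run_check_event(state_dx,
                               list(channel = "organised_screen"),
                               params = p, u = 0.5), "before the first")
  expect_error(run_check_event(state_free,
                               list(channel = "surveillance"),
                               params = p, u = 0.5), "after a first")
})

test_that("surveillance schedules follow stage/risk intensity", {
  p <- default_parameters()
  s_int <- surveillance_schedule("III", "high", p, diagnosis_age = 60)
  expect_equal(diff(s_int)[1], 0.5)
  s_std <- surveillance_schedule("I", "average", p, diagnosis_age = 60)
  expect_equal(diff(s_std)[1], 1.0)
  # high risk alone is enough for intensive surveillance
  expect_equal(diff(surveillance_schedule("I", "high", p, 60))[1], 0.5)
  # offsets run to the age cap
  expect_lte(60 + max(s_std), 85)
  expect_gt(60 + max(s_std), 84)
  # attendance decays with time since diagnosis
  expect_lte(melscreen:::.surveillance_attendance(10, "I",
                                                  "superficial_spreading",
                                                  p),
             melscreen:::.surveillance_attendance(1, "I",
                                                  "superficial_spreading",
                                                  p))
})

test_that("channel gating holds across a whole simulated cohort", {
  co <- shared_cohort_10k()
  ev <- events_table(co)
  tt <- tumours_table(co)
  dx1 <- tt[tt$diagnosed %in% TRUE & tt$tumour_index == 1L,
            c("individual_id", "diagnosis_age")]
  m <- merge(ev, dx1, by = "individual_id", all.x = TRUE)
  pre <- is.na(m$diagnosis_age) | m$age <= m$diagnosis_age
  # no organised/routine checks after the first diagnosis
  routine_like <- m$channel %in% c("routine_check", "organised_screen")
  expect_true(all(pre[routine_like]))
  # no surveillance before it
  surv <- m$channel %in% "surveillance"
  expect_true(all(!is.na(m$diagnosis_age[surv]) &
                    m$age[surv] >= m$diagnosis_age[surv]))
})

test_that("screening shortens dwell at diagnosis under the same seed", {
  p <- default_parameters()
  pol <- screening_policy(interval = 1)
  a <- simulate_cohort(p, 3000, 55, policy = pol, keep_events = FALSE)
  b <- simulate_cohort(p, 3000, 55, policy = NULL, keep_events = FALSE)
  ta <- tumours_table(a); tb <- tumours_table(b)
  da <- ta[ta$diagnosed %in% TRUE & ta$tumour_index == 1L, ]
  db <- tb[tb$diagnosed %in% TRUE & tb$tumour_index == 1L, ]
  expect_lte(mean(da$dwell_at_diagnosis), mean(db$dwell_at_diagnosis))
})
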