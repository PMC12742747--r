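test_that("discounting closed forms", {
  expect_equal(discount(100, 5, 0), 100)
  expect_equal(discount(100, 0, 0.05), 100)
  expect_equal(discount(100, 1, 0.05), 100 / 1.05)
  expect_equal(discount(100, 10, 0.05), 100 / 1.05^10)
  expect_error(discount(1, -1, 0.05), "time")
  expect_error(discount(1, 1, -0.01), "rate")
})

test_that("empty history accrues zero cost and 70 undiscounted LY", {
  p <- default_parameters()
  ev <- toy_event_matrix(85, melscreen:::.mel_event_types[["age_cap_exit"]])
  h <- toy_history(ev, exit_age = 85)
  a <- accrue(h, p)
  expect_equal(a$cost, 0)
  expect_equal(a$undiscounted_life_years, 70)
  expect_equal(a$undiscounted_qalys, 70)  # well weight 1
  rho <- log(1.05)
  expect_equal(a$life_years, (1 - exp(-rho * 70)) / rho)
  # discounted <= undiscounted at positive rate
  expect_lte(a$life_years, a$undiscounted_life_years)
})

test_that("hand-enumerated 3-event toy accrual matches to 1e-9", {
  p <- default_parameters()
  tf <- p$economics$tariff
  et <- melscreen:::.mel_event_types
  # one routine check at 40 (false positive), one opportunistic check at
  # 50, diagnosis at 50 (stage II, b1_4mm), exit (other cause) at 60
  tum <- toy_tumour(1, emergence_age = 46, diagnosis_age = 50,
                    stage = "II", breslow = "b1_4mm")
  ev <- toy_event_matrix(
    age = c(40, 46, 50, 50, 60),
    type = c(et[["clinician_visit"]], et[["melanoma_emergence"]],
             et[["clinician_visit"]], et[["diagnosis"]],
             et[["other_death"]]),
    channel = c(2L, 0L, 1L, 1L, 0L),
    outcome = c(1L, 0L, 0L, 0L, 0L),
    tumour = c(0L, 1L, 0L, 1L, 0L))
  h <- toy_history(ev, tumours = list(tum), exit_age = 60,
                   exit_cause = "other_death")
  a <- accrue(h, p)
  r <- 0.05; rho <- log(1 + r)
  adj <- p$economics$keratinocyte_adjunct_cost
  hand <- (tf$check_cost$routine_check + adj + tf$false_positive_workup) /
    (1 + r)^25 +
    (tf$check_cost$opportunistic_visit + adj) / (1 + r)^35 +
    (tf$diagnostic_excision + tf$treatment_initial$II) / (1 + r)^35 +
    tf$treatment_continuing$II *
    (exp(-rho * 35) - exp(-rho * 40)) / rho
  expect_equal(a$cost, hand, tolerance = 1e-9)
  # QALYs: well to 50, stage-II weight afterwards
  w2 <- p$economics$utilities$II
  hand_qaly <- (exp(-rho * 0) - exp(-rho * 35)) / rho +
    w2 * (exp(-rho * 35) - exp(-rho * 45)) / rho
  expect_equal(a$qalys, hand_qaly, tolerance = 1e-9)
  expect_lte(a$qalys, a$life_years)
})

test_that("every skin check carries the keratinocyte adjunct once", {
  p <- default_parameters()
  et <- melscreen:::.mel_event_types
  ev <- toy_event_matrix(age = c(30, 40, 85),
                         type = c(et[["clinician_visit"]],
                                  et[["screening_round"]],
                                  et[["age_cap_exit"]]),
                         channel = c(1L, 3L, 0L))
  h <- toy_history(ev)
  base <- accrue(h, p)$cost
  q <- p
  q$economics$keratinocyte_adjunct_cost <- 0
  no_adj <- accrue(h, q)$cost
  adj <- p$economics$keratinocyte_adjunct_cost
  expect_equal(base - no_adj,
               discount(adj, 15, 0.05) + discount(adj, 25, 0.05))
})

test_that("CEA identities: increments, ICER, NMB, decision agreement", {
  p <- default_parameters()
  co <- simulate_cohort(p, 300, 2)
  cea0 <- compare_strategies(co, co, p)
  expect_equal(cea0$incremental_cost, 0)
  expect_equal(cea0$incremental_qaly, 0)
  expect_equal(cea0$nmb, 0)
  expect_true(cea0$icer_undefined)

  pol <- screening_policy()
  a <- simulate_cohort(p, 400, 8, policy = pol)
  b <- simulate_cohort(p, 400, 8, policy = NULL)
  cea <- compare_strategies(a, b, p)
  if (!cea$icer_undefined && cea$incremental_qaly > 0 &&
      cea$incremental_cost > 0) {
    expect_equal(cea$icer_per_qaly,
                 cea$incremental_cost / cea$incremental_qaly)
    # NMB decision agrees with ICER-vs-WTP when both increments positive
    expect_identical(cea$nmb > 0, cea$icer_per_qaly < cea$wtp)
  }
  expect_equal(cea$nmb,
               cea$wtp * cea$incremental_qaly - cea$incremental_cost)
  expect_error(compare_strategies(a, simulate_cohort(p, 400, 9), p),
               "common random numbers")
})

test_that("NMB decision boundary at wtp x dQALY = dCost", {
  nmb <- 50000 * 1 - 50000
  expect_equal(nmb, 0)
})

test_that("overdiagnosis on a hand-paired toy cohort", {
  mk_pair <- function(id, screened_dx, counterfactual_dx) {
    ts <- toy_tumour(1, emergence_age = 60, diagnosis_age = 61,
                     channel = "organised_screen")
    hs <- toy_history(NULL, tumours = if (screened_dx) list(ts)
                      else list(), exit_age = 80,
                      exit_cause = "other_death")
    tu <- toy_tumour(1, emergence_age = 60, diagnosis_age = 70,
                     diagnosed = counterfactual_dx)
    hu <- toy_history(NULL, tumours = list(tu), exit_age = 80,
                      exit_cause = "other_death")
    list(s = hs, u = hu)
  }
  pairs <- list(mk_pair(1, TRUE, TRUE), mk_pair(2, TRUE, FALSE),
                mk_pair(3, TRUE, FALSE), mk_pair(4, TRUE, TRUE),
                mk_pair(5, TRUE, TRUE))
  sc <- toy_cohort(lapply(pairs, `[[`, "s"), seed = 7)
  un <- toy_cohort(lapply(pairs, `[[`, "u"), seed = 7)
  od <- overdiagnosis_estimate(sc, un)
  expect_identical(od$n_screen_detected, 5L)
  expect_identical(od$n_overdiagnosed, 2L)
  expect_equal(od$proportion, 2 / 5)
  expect_error(overdiagnosis_estimate(sc, toy_cohort(list(
    toy_history(NULL)), seed = 8)), "paired")
})

test_that("overdiagnosis extremes under simulation", {
  # no other-cause death and clinical diagnosis effectively certain:
  # counterfactual diagnosis always happens, overdiagnosis 0
  p <- flat_params(lambda_mel = 0.01, lambda_oc = 0, visits = 1,
                   uptake = 0)
  for (h in names(p$detection$curves))
    p$detection$curves[[h]] <- list(p0 = 0.95, pmax = 0.95, rate = 0)
  p$detection$period$start_factor <- 1
  pol <- screening_policy(age_range = c(20, 80), start_year = 1950,
                          interval = 1, participation = 1,
                          sensitivity = 1)
  a <- simulate_cohort(p, 400, 5, policy = pol, keep_events = FALSE)
  b <- simulate_cohort(p, 400, 5, policy = NULL, keep_events = FALSE)
  od <- overdiagnosis_estimate(a, b)
  expect_gt(od$n_screen_detected, 10)
  expect_equal(od$proportion, 0)
  # no detection outside screening and certain early other-cause death:
  # counterfactual diagnosis never happens, overdiagnosis 1
  q <- flat_params(lambda_mel = 0.05, lambda_oc = 0.08, visits = 0,
                   uptake = 0)
  for (h in names(q$detection$curves))
    q$detection$curves[[h]] <- list(p0 = 0.9, pmax = 0.9, rate = 0)
  q$detection$period$start_factor <- 1
  a2 <- simulate_cohort(q, 400, 6, policy = pol, keep_events = FALSE)
  b2 <- simulate_cohort(q, 400, 6, policy = NULL, keep_events = FALSE)
  od2 <- overdiagnosis_estimate(a2, b2)
  expect_gt(od2$n_screen_detected, 10)
  expect_equal(od2$proportion, 1)
})

test_that("budget impact: 5 annual rows, identity zero, linear scaling", {
  p <- default_parameters()
  pol <- screening_policy()
  a <- simulate_cohort(p, 300, 12, policy = pol)
  b <- simulate_cohort(p, 300, 12, policy = NULL)
  bi <- budget_impact(a, b, p, 1e6, 2030)
  expect_identical(nrow(bi), 5L)
  expect_equal(bi$year, 2030:2034)
  bi0 <- budget_impact(a, a, p, 1e6, 2030)
  expect_true(all(bi0$incremental_cost == 0))
  bi2 <- budget_impact(a, b, p, 2e6, 2030)
  expect_equal(bi2$incremental_cost, 2 * bi$incremental_cost)
  expect_error(budget_impact(a, b, p, 1e6, 2030, horizon = 0),
               "horizon")
})
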