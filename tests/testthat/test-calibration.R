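test_that("summaries on a hand-built cohort match hand-computed rates", {
  # three individuals: one male diagnosed at 50, exits at 60; one male
  # exits at 45 undiagnosed; one female exits at 85
  h1 <- toy_history(NULL, tumours = list(toy_tumour(1, emergence_age = 48,
                                                    diagnosis_age = 50)),
                    exit_age = 60, exit_cause = "other_death")
  h2 <- toy_history(NULL, exit_age = 45, exit_cause = "other_death")
  h3 <- toy_history(NULL, exit_age = 85, exit_cause = "age_cap",
                    sex = "female")
  co <- toy_cohort(list(h1, h2, h3))
  sm <- compute_summaries(co, summary_strata(c(45, 65), by_sex = TRUE))
  # male person-years in [45,65): (60-45) + (45-45) = 15; 1 diagnosis
  inc_m <- sm$value[sm$statistic == "incidence" & sm$sex == "male"]
  expect_equal(inc_m, 1 / 15 * 1e5)
  # female: 20 person-years, no diagnoses
  inc_f <- sm$value[sm$statistic == "incidence" & sm$sex == "female"]
  expect_equal(inc_f, 0)
  # melanoma-free cohort: incidence 0, second-primary proportion missing
  co0 <- toy_cohort(list(h2, h3))
  sm0 <- compute_summaries(co0, summary_strata(c(45, 65)))
  # melanoma-free: zero incidence where person-time exists, missing (not
  # zero) where it does not
  inc0 <- sm0[sm0$statistic == "incidence", ]
  expect_equal(inc0$value[inc0$sex == "female"], 0)
  expect_true(is.na(inc0$value[inc0$sex == "male"]))  # 0 person-years
  expect_true(is.na(sm0$value[sm0$statistic == "second_primary_10y"]))
})

test_that("summaries are additive across cohort halves", {
  p <- default_parameters()
  full <- simulate_cohort(p, 400, 3, keep_events = FALSE)
  h1 <- simulate_cohort(p, 200, 3, ids = 1:200, keep_events = FALSE)
  h2 <- simulate_cohort(p, 200, 3, ids = 201:400, keep_events = FALSE)
  pooled <- toy_cohort(c(h1$histories, h2$histories), seed = 3)
  # pooled ids get renumbered by toy_cohort; rates only need exits/tumours
  s_full <- compute_summaries(full)
  s_pool <- compute_summaries(pooled)
  expect_equal(s_full$value, s_pool$value)
})

test_that("empty strata are reported missing, not zero", {
  h <- toy_history(NULL, exit_age = 40, exit_cause = "other_death")
  co <- toy_cohort(list(h))
  sm <- compute_summaries(co, summary_strata(c(15, 45, 85)))
  v85 <- sm$value[sm$statistic == "incidence" & sm$sex == "male" &
                    sm$age_low == 45]
  expect_true(is.na(v85))
})

test_that("distance is a positive-definite weighted quadratic form", {
  co <- simulate_cohort(default_parameters(), 300, 6,
                        keep_events = FALSE)
  sm <- compute_summaries(co)
  targets <- sm[!is.na(sm$value), ]
  targets$weight <- 1
  expect_equal(target_distance(sm, targets), 0)
  t2 <- targets
  t2$value[1] <- t2$value[1] * 1.1 + 1
  d2 <- target_distance(sm, t2)
  expect_gt(d2, 0)
  # doubling one weight doubles its contribution
  t3 <- t2
  t3$weight[1] <- 2
  expect_equal(target_distance(sm, t3), 2 * d2)
  # missing stratum errors, naming the statistic
  t4 <- targets[1, ]
  t4$statistic <- "no_such_statistic"
  expect_error(target_distance(sm, t4), "no_such_statistic")
})

test_that("priors sample within support and respect invariants", {
  pr <- prior("baseline_incidence.scale", "uniform", 0.5, 2)
  set.seed(1)
  x <- melscreen:::.prior_sample(pr, 1000)
  expect_true(all(x >= 0.5 & x <= 2))
  prb <- prior("subsequent_histology_concordance", "beta", 5, 2)
  xb <- melscreen:::.prior_sample(prb, 1000)
  expect_true(all(xb >= 0 & xb <= 1))
  expect_equal(melscreen:::.prior_density(pr, 3), 0)
})

# cheap, fast-simulating parameterisation used for ABC checks: flat
# emergence hazard, immediate near-certain detection, quiet background
abc_params <- function() {
  p <- flat_params(lambda_mel = 0.002, lambda_oc = 0.005, visits = 0.4,
                   uptake = 0)
  for (h in names(p$detection$curves))
    p$detection$curves[[h]] <- list(p0 = 0.9, pmax = 0.9, rate = 0)
  p$detection$period$start_factor <- 1
  p$post_diagnosis_risk_multipliers <- rep(1.5, 4)
  p
}

abc_targets <- function(truth, n = 2000, seed = 101) {
  p <- param_set(abc_params(), "baseline_incidence.scale", truth)
  sm <- compute_summaries(simulate_cohort(p, n, seed,
                                          keep_events = FALSE),
                          summary_strata(c(15, 85), by_sex = FALSE))
  tg <- sm[sm$statistic == "incidence" & !is.na(sm$value), ]
  tg$weight <- 1
  tg
}

test_that("distance is minimised at the generating parameter value", {
  truth <- 1.2
  tg <- abc_targets(truth, n = 4000)
  grid <- c(0.6, 0.9, 1.2, 1.5, 1.8)
  d <- vapply(seq_along(grid), function(i) {
    p <- param_set(abc_params(), "baseline_incidence.scale", grid[i])
    co <- simulate_cohort(p, 4000, 500 + i, keep_events = FALSE)
    target_distance(compute_summaries(co, summary_strata(c(15, 85),
                                                         by_sex = FALSE)),
                    tg)
  }, numeric(1))
  expect_equal(grid[which.min(d)], truth)
})

test_that("ABC-SMC thresholds shrink and the posterior concentrates", {
  tg <- abc_targets(1.3)
  fit <- calibrate_abc(abc_params(),
                       list(prior("baseline_incidence.scale", "uniform",
                                  0.5, 2.5)),
                       tg, strata = summary_strata(c(15, 85),
                                                   by_sex = FALSE),
                       n_population = 10, n_generations = 3,
                       n_per_draw = 300, seed = 5)
  expect_s3_class(fit, "mel_abc")
  meds <- vapply(split(fit$history$distance, fit$history$generation),
                 stats::median, numeric(1))
  expect_true(all(diff(meds) <= 1e-9))
  # no particle violates parameter invariants
  expect_true(all(fit$particles[["baseline_incidence.scale"]] > 0))
  ci <- posterior_interval(fit)
  expect_lt(ci[1], ci[2])
  # reproducible from seed
  fit2 <- calibrate_abc(abc_params(),
                        list(prior("baseline_incidence.scale", "uniform",
                                   0.5, 2.5)),
                        tg, strata = summary_strata(c(15, 85),
                                                    by_sex = FALSE),
                        n_population = 10, n_generations = 3,
                        n_per_draw = 300, seed = 5)
  expect_identical(fit$particles, fit2$particles)
})

test_that("degenerate point prior returns the prior", {
  tg <- abc_targets(1.0)
  fit <- calibrate_abc(abc_params(),
                       list(prior("baseline_incidence.scale", "uniform",
                                  1.0, 1.0 + 1e-9)),
                       tg, strata = summary_strata(c(15, 85),
                                                   by_sex = FALSE),
                       n_population = 4, n_generations = 2,
                       n_per_draw = 200, seed = 9)
  expect_true(all(abs(fit$particles[["baseline_incidence.scale"]] - 1) <
                    1e-6))
})

test_that("an impossible budget fails loudly with diagnostics", {
  tg <- abc_targets(1.0)
  expect_error(
    calibrate_abc(abc_params(),
                  list(prior("baseline_incidence.scale", "uniform",
                             0.5, 2.5)),
                  tg, strata = summary_strata(c(15, 85), by_sex = FALSE),
                  n_population = 10, n_generations = 3,
                  n_per_draw = 100, budget = 5, seed = 2),
    "budget exhausted")
})

test_that("PSA reduces to a paired run for a degenerate posterior", {
  p <- abc_params()
  draws <- data.frame(`baseline_incidence.scale` = 1.1,
                      check.names = FALSE)
  pol <- screening_policy(interval = 2)
  psa <- probabilistic_sensitivity_analysis(p, draws, pol,
                                            n_per_draw = 300, seed = 44)
  expect_identical(nrow(psa), 1L)
  q <- param_set(p, "baseline_incidence.scale", 1.1)
  sim_seed <- (44 * 131 + 1 * 524287) %% 2147483629
  a <- simulate_cohort(q, 300, sim_seed, policy = pol)
  b <- simulate_cohort(q, 300, sim_seed, policy = NULL)
  cea <- compare_strategies(a, b, q)
  expect_equal(psa$nmb, cea$nmb)
  # identical policies: zero increments in every draw
  psa0 <- probabilistic_sensitivity_analysis(p, draws, pol,
                                             comparator = pol,
                                             n_per_draw = 200, seed = 44)
  expect_equal(psa0$incremental_cost, 0)
  expect_equal(psa0$incremental_qaly, 0)
  # acceptability is the mean of the per-draw indicators
  draws5 <- data.frame(`baseline_incidence.scale` = seq(0.9, 1.3, 0.1),
                       check.names = FALSE)
  psa5 <- probabilistic_sensitivity_analysis(p, draws5, pol,
                                             n_per_draw = 150, seed = 3)
  expect_equal(attr(psa5, "acceptability"), mean(psa5$cost_effective))
})
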