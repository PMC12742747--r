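# Calibration: registry-style summary statistics, a weighted quadratic
# distance, ABC-SMC posterior sampling (the simulator's likelihood is
# intractable, so calibration is likelihood-free), and probabilistic
# sensitivity analysis over the posterior.

#' Default stratification for registry-style summaries
#'
#' @param age_breaks Age-band limits.
#' @param by_sex Stratify by sex?
#' @return A strata-definition list.
#' @export
summary_strata <- function(age_breaks = c(15, 45, 65, 85), by_sex = TRUE) {
  list(age_breaks = as.numeric(age_breaks), by_sex = isTRUE(by_sex))
}

# person-years spent by one interval [entry, exit) inside [lo, hi)
.py_in_band <- function(entry, exit, lo, hi)
  pmax(pmin(exit, hi) - pmax(entry, lo), 0)

#' Registry-style summary statistics of a cohort
#'
#' Computes, per stratum (age band x sex), melanoma incidence (diagnoses
#' of any primary) and melanoma-specific mortality per 100,000
#' person-years, with person-time accrued between entry and exit; plus
#' the cohort-level proportion of first-primary patients diagnosed with a
#' second primary within 10 years (among those with at least 10 years of
#' follow-up after the first diagnosis) and the stage distribution at
#' diagnosis. Empty strata yield `NA` rates, not zero.
#'
#' @param cohort A `mel_cohort`.
#' @param strata A strata definition from [summary_strata()].
#' @return A `data.table` with columns `statistic`, `sex`, `age_low`,
#'   `age_high`, `value`.
#' @export
compute_summaries <- function(cohort, strata = summary_strata()) {
  if (!inherits(cohort, "mel_cohort") || cohort$n < 1L)
    stop("`cohort` must be a non-empty mel_cohort")
  ex <- .exit_table(cohort)
  tt <- tumours_table(cohort)
  entry <- cohort$entry_age
  brk <- strata$age_breaks
  sexes <- if (strata$by_sex) c("male", "female") else "all"
  rows <- list()
  for (sx in sexes) {
    exs <- if (sx == "all") ex else ex[ex$sex == sx, ]
    for (i in seq_len(length(brk) - 1L)) {
      lo <- brk[i]; hi <- brk[i + 1L]
      py <- sum(.py_in_band(entry, exs$exit_age, lo, hi))
      if (nrow(tt)) {
        tts <- if (sx == "all") tt else tt[tt$sex == sx, ]
        ndx <- sum(tts$diagnosed & tts$diagnosis_age >= lo &
                     tts$diagnosis_age < hi, na.rm = TRUE)
      } else ndx <- 0L
      ndeath <- sum(exs$exit_cause == "melanoma_death" &
                      exs$exit_age >= lo & exs$exit_age < hi)
      inc <- if (py > 0) ndx / py * 1e5 else NA_real_
      mor <- if (py > 0) ndeath / py * 1e5 else NA_real_
      rows[[length(rows) + 1L]] <- data.table::data.table(
        statistic = c("incidence", "mortality"), sex = sx,
        age_low = lo, age_high = hi, value = c(inc, mor))
    }
  }
  sp <- second_primary_proportion(cohort)
  rows[[length(rows) + 1L]] <- data.table::data.table(
    statistic = "second_primary_10y", sex = NA_character_,
    age_low = NA_real_, age_high = NA_real_, value = sp)
  if (nrow(tt)) {
    dx <- tt[tt$diagnosed %in% TRUE, ]
  } else dx <- tt
  for (st in .mel_stages) {
    v <- if (nrow(dx) > 0)
      mean(dx$stage_at_diagnosis == st) else NA_real_
    rows[[length(rows) + 1L]] <- data.table::data.table(
      statistic = paste0("stage_", st), sex = NA_character_,
      age_low = NA_real_, age_high = NA_real_, value = v)
  }
  data.table::rbindlist(rows)
}

#' Proportion with a second primary within a window of the first diagnosis
#'
#' Among individuals with a diagnosed first primary and at least `window`
#' years of follow-up before exit, the proportion diagnosed with a second
#' primary within `window` years of the first diagnosis. Returns `NA`
#' when the denominator is empty.
#'
#' @param cohort A `mel_cohort`.
#' @param window Follow-up window in years (default 10).
#' @return Proportion in \[0,1\] or `NA`.
#' @export
second_primary_proportion <- function(cohort, window = 10) {
  tt <- tumours_table(cohort)
  if (!nrow(tt)) return(NA_real_)
  dx <- tt[tt$diagnosed %in% TRUE, ]
  if (!nrow(dx)) return(NA_real_)
  first <- dx[dx$tumour_index == 1L, ]
  first <- first[first$exit_age - first$diagnosis_age >= window, ]
  if (!nrow(first)) return(NA_real_)
  second <- dx[dx$tumour_index == 2L,
               c("individual_id", "diagnosis_age")]
  names(second)[2L] <- "second_dx_age"
  m <- merge(first, second, by = "individual_id", all.x = TRUE)
  mean(!is.na(m$second_dx_age) &
         m$second_dx_age - m$diagnosis_age <= window)
}

#' Weighted quadratic distance between summaries and targets
#'
#' Weighted squared relative error, zero iff every target is matched
#' exactly. Targets with observed value 0 contribute absolute squared
#' error. A target stratum missing from the summaries (or simulated as
#' `NA`) is an error naming the target.
#'
#' @param summaries Summary table from [compute_summaries()].
#' @param targets Data frame with columns `statistic`, `sex`, `age_low`,
#'   `age_high`, `value` and `weight` (> 0).
#' @return Non-negative scalar.
#' @export
target_distance <- function(summaries, targets) {
  if (any(targets$weight <= 0)) stop("target weights must be > 0")
  total <- 0
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    sel <- summaries$statistic == tg$statistic &
      (is.na(tg$sex) | (!is.na(summaries$sex) & summaries$sex == tg$sex)) &
      (is.na(tg$age_low) | (!is.na(summaries$age_low) &
                              abs(summaries$age_low - tg$age_low) < 1e-9))
    if (!any(sel))
      stop("target stratum not present in summaries: ", tg$statistic,
           " sex=", tg$sex, " age_low=", tg$age_low)
    sim <- summaries$value[which(sel)[1L]]
    if (is.na(sim))
      stop("simulated summary is missing for target: ", tg$statistic,
           " sex=", tg$sex, " age_low=", tg$age_low)
    scale <- if (abs(tg$value) > 1e-12) tg$value else 1
    total <- total + tg$weight * ((sim - tg$value) / scale)^2
  }
  total
}

# ---- priors ------------------------------------------------------------

#' Prior on one parameter path
#'
#' @param path Dotted path into the parameter set (see [param_get()]).
#' @param distribution One of `"uniform"`, `"loguniform"`, `"normal"`,
#'   `"beta"`.
#' @param a,b Hyperparameters: min/max (uniform, loguniform), mean/sd
#'   (normal), shape1/shape2 (beta).
#' @return A `mel_prior` list.
#' @export
prior <- function(path, distribution = c("uniform", "loguniform",
                                         "normal", "beta"),
                  a, b) {
  distribution <- match.arg(distribution)
  structure(list(path = path, distribution = distribution,
                 a = a, b = b), class = "mel_prior")
}

.prior_sample <- function(pr, n) {
  switch(pr$distribution,
         uniform = stats::runif(n, pr$a, pr$b),
         loguniform = exp(stats::runif(n, log(pr$a), log(pr$b))),
         normal = stats::rnorm(n, pr$a, pr$b),
         beta = stats::rbeta(n, pr$a, pr$b))
}

.prior_density <- function(pr, x) {
  switch(pr$distribution,
         uniform = stats::dunif(x, pr$a, pr$b),
         loguniform = ifelse(x >= pr$a & x <= pr$b,
                             1 / (x * (log(pr$b) - log(pr$a))), 0),
         normal = stats::dnorm(x, pr$a, pr$b),
         beta = stats::dbeta(x, pr$a, pr$b))
}

.prior_width <- function(pr) {
  switch(pr$distribution,
         uniform = ,
         loguniform = pr$b - pr$a,
         normal = pr$b,
         beta = 1)
}

# ---- ABC-SMC -----------------------------------------------------------

#' Calibrate parameters by ABC-SMC
#'
#' Approximate Bayesian computation with sequential Monte Carlo: an
#' initial population is drawn from the priors; each subsequent
#' generation resamples and perturbs accepted particles (Gaussian kernel,
#' twice the weighted empirical variance) and accepts proposals whose
#' simulated-summary distance falls below a quantile-based threshold
#' (median of the previous generation's accepted distances), so
#' thresholds shrink across generations. Particle weights follow the
#' standard prior/kernel importance ratio. Reproducible from `seed`.
#'
#' @param params Baseline `mel_parameters`; calibrated paths are
#'   overwritten per particle.
#' @param priors List of [prior()] objects (at least one).
#' @param targets Target table (see [target_distance()]; at least one
#'   row).
#' @param strata Strata definition used for simulated summaries.
#' @param n_population Particles per generation.
#' @param n_generations Number of SMC generations.
#' @param n_per_draw Cohort size simulated per particle evaluation.
#' @param budget Maximum number of simulator evaluations; exceeded budget
#'   aborts with diagnostics.
#' @param seed Integer seed controlling every draw.
#' @param policy Policy under which the simulator is run (default none).
#' @return Object of class `mel_abc`: `particles` (final-generation
#'   `data.table` of parameter values, distance, weight), `history` (all
#'   generations), `thresholds`, `n_evaluations`.
#' @export
calibrate_abc <- function(params, priors, targets,
                          strata = summary_strata(),
                          n_population = 16L, n_generations = 3L,
                          n_per_draw = 500L,
                          budget = 20L * n_population * n_generations,
                          seed = 1L, policy = NULL) {
  if (!length(priors)) stop("at least one prior is required")
  if (!nrow(targets)) stop("at least one target is required")
  paths <- vapply(priors, `[[`, character(1), "path")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n_eval <- 0L
  evaluate <- function(theta) {
    p <- params
    for (j in seq_along(paths)) p <- param_set(p, paths[j], theta[j])
    if (nrow(validate_parameters(p))) return(Inf)
    n_eval <<- n_eval + 1L
    sim_seed <- (seed * 7919 + n_eval * 104729) %% 2147483629
    co <- simulate_cohort(p, n_per_draw, sim_seed, policy = policy,
                          keep_events = FALSE)
    target_distance(compute_summaries(co, strata), targets)
  }

  npar <- length(priors)
  history <- list()
  thresholds <- numeric(0)
  theta <- matrix(NA_real_, n_population, npar,
                  dimnames = list(NULL, paths))
  dist <- numeric(n_population)
  w <- rep(1 / n_population, n_population)

  for (g in seq_len(n_generations)) {
    if (g == 1L) {
      for (i in seq_len(n_population)) {
        repeat {
          cand <- vapply(priors, .prior_sample, numeric(1), n = 1L)
          if (all(vapply(seq_len(npar), function(j)
            .prior_density(priors[[j]], cand[j]) > 0, logical(1)))) break
        }
        theta[i, ] <- cand
        dist[i] <- evaluate(cand)
        if (n_eval > budget)
          stop("ABC budget exhausted after ", n_eval,
               " evaluations in generation ", g,
               "; increase `budget` or reduce the population")
      }
      eps <- Inf
    } else {
      eps <- stats::median(dist)
      kern_sd <- sqrt(pmax(2 * apply(theta, 2L, function(x)
        sum(w * (x - sum(w * x))^2)), (vapply(priors, .prior_width,
                                              numeric(1)) * 1e-6)^2))
      new_theta <- matrix(NA_real_, n_population, npar,
                          dimnames = list(NULL, paths))
      new_dist <- numeric(n_population)
      new_w <- numeric(n_population)
      for (i in seq_len(n_population)) {
        repeat {
          k <- sample.int(n_population, 1L, prob = w)
          cand <- stats::rnorm(npar, theta[k, ], kern_sd)
          pd <- vapply(seq_len(npar), function(j)
            .prior_density(priors[[j]], cand[j]), numeric(1))
          if (any(pd <= 0)) next
          d <- evaluate(cand)
          if (n_eval > budget)
            stop("ABC budget exhausted after ", n_eval,
                 " evaluations in generation ", g,
                 "; last threshold ", signif(eps, 4))
          if (d <= eps) break
        }
        new_theta[i, ] <- cand
        new_dist[i] <- d
        denom <- sum(w * vapply(seq_len(n_population), function(k2)
          prod(stats::dnorm(cand, theta[k2, ], kern_sd)), numeric(1)))
        new_w[i] <- prod(pd) / max(denom, 1e-300)
      }
      theta <- new_theta; dist <- new_dist
      w <- new_w / sum(new_w)
    }
    thresholds <- c(thresholds, eps)
    history[[g]] <- data.table::data.table(
      generation = g, theta, distance = dist, weight = w)
  }

  particles <- history[[n_generations]]
  structure(list(particles = particles,
                 history = data.table::rbindlist(history),
                 thresholds = thresholds, paths = paths,
                 n_evaluations = n_eval),
            class = "mel_abc")
}

#' @export
print.mel_abc <- function(x, ...) {
  cat("<mel_abc>", length(x$paths), "parameter(s),",
      max(x$history$generation), "generations,", x$n_evaluations,
      "simulator evaluations\n")
  for (p in x$paths) {
    v <- x$particles[[p]]
    cat("  ", p, ": median ", signif(stats::median(v), 4), " [",
        signif(stats::quantile(v, 0.025), 4), ", ",
        signif(stats::quantile(v, 0.975), 4), "]\n", sep = "")
  }
  invisible(x)
}

#' Central posterior interval from an ABC fit
#'
#' @param fit A `mel_abc` object.
#' @param path Parameter path (defaults to the first calibrated path).
#' @param level Interval mass (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
posterior_interval <- function(fit, path = fit$paths[1L], level = 0.95) {
  v <- fit$particles[[path]]
  a <- (1 - level) / 2
  stats::quantile(v, c(a, 1 - a), names = FALSE)
}

#' Probabilistic sensitivity analysis over an ABC posterior
#'
#' For each posterior draw the policy pair is simulated under common
#' random numbers, incremental discounted cost and QALYs are computed,
#' and the cost-effectiveness indicator at the willingness-to-pay
#' threshold is recorded. The acceptability fraction is the mean of the
#' per-draw indicators.
#'
#' @param params Baseline `mel_parameters`.
#' @param fit A `mel_abc` object (or a data frame of parameter draws with
#'   columns named by path).
#' @param policy Strategy `mel_policy`.
#' @param comparator Comparator policy (default `NULL`, the opportunistic
#'   setting).
#' @param n_per_draw Cohort size per draw.
#' @param seed Integer seed (same seed is reused across the two arms of
#'   each draw: common random numbers).
#' @param n_draws Number of posterior draws to evaluate (default all).
#' @return A `data.table` with per-draw incremental cost, QALY, NMB and
#'   indicator; attribute `acceptability` holds the acceptability
#'   fraction.
#' @export
probabilistic_sensitivity_analysis <- function(params, fit, policy,
                                               comparator = NULL,
                                               n_per_draw = 500L,
                                               seed = 1L,
                                               n_draws = NULL) {
  draws <- if (inherits(fit, "mel_abc")) fit$particles else fit
  paths <- if (inherits(fit, "mel_abc")) fit$paths
           else setdiff(names(draws), c("generation", "distance", "weight"))
  if (!nrow(draws)) stop("posterior is empty")
  if (is.null(n_draws)) n_draws <- nrow(draws)
  n_draws <- min(n_draws, nrow(draws))
  wtp <- params$economics$wtp_threshold
  out <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    p <- params
    for (pt in paths) p <- param_set(p, pt, draws[[pt]][i])
    sim_seed <- (seed * 131 + i * 524287) %% 2147483629
    a <- simulate_cohort(p, n_per_draw, sim_seed, policy = policy)
    b <- simulate_cohort(p, n_per_draw, sim_seed, policy = comparator)
    cea <- compare_strategies(a, b, p)
    out[[i]] <- data.table::data.table(
      draw = i, incremental_cost = cea$incremental_cost,
      incremental_qaly = cea$incremental_qaly,
      nmb = cea$nmb, cost_effective = as.integer(cea$nmb > 0))
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "acceptability", mean(res$cost_effective))
  data.table::setattr(res, "wtp", wtp)
  res
}
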