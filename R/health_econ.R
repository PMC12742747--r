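# Health economics: continuous discounting at event times, lifetime cost
# and QALY accrual on event logs, incremental cost-effectiveness and net
# monetary benefit, counterfactual-paired overdiagnosis, and a 5-year
# undiscounted budget impact. Payer perspective, lifetime horizon.

#' Discount a cost or QALY amount
#'
#' Continuous-time discounting on an annual base:
#' `amount / (1 + rate)^time`.
#'
#' @param amount Currency or QALY amount.
#' @param time Years from the reference time (>= 0).
#' @param rate Annual discount rate (fraction, >= 0).
#' @return Discounted value.
#' @export
discount <- function(amount, time, rate) {
  if (any(time < 0)) stop("time must be >= 0")
  if (any(rate < 0)) stop("rate must be >= 0")
  amount / (1 + rate)^time
}

# integral of e^{-rho (t - ref)} dt over [a, b]
.disc_integral <- function(a, b, ref, rho) {
  if (b <= a) return(0)
  if (rho <= 0) return(b - a)
  (exp(-rho * (a - ref)) - exp(-rho * (b - ref))) / rho
}

# Utility trajectory: well weight until the first diagnosis, then the
# weight of the worst stage diagnosed so far.
.utility_segments <- function(h, params) {
  utl <- params$economics$utilities
  ea <- attr(h, "entry_age", exact = TRUE)
  if (is.null(ea)) ea <- 15
  dx <- list()
  for (tm in h$tumours)
    if (isTRUE(tm$diagnosed))
      dx[[length(dx) + 1L]] <- c(tm$diagnosis_age,
                                 match(tm$stage_at_diagnosis, .mel_stages))
  if (!length(dx))
    return(data.frame(from = ea, to = h$exit_age, w = utl$well))
  m <- do.call(rbind, dx)
  m <- m[order(m[, 1L]), , drop = FALSE]
  worst <- cummax(m[, 2L])
  from <- c(ea, m[, 1L])
  to <- c(m[, 1L], h$exit_age)
  w <- c(utl$well, unlist(utl[.mel_stages])[worst])
  keep <- to > from
  data.frame(from = from[keep], to = to[keep], w = w[keep])
}

# Cost rows (age, cost) for one history's events.
.cost_rows <- function(h, params) {
  ec <- params$economics
  tf <- ec$tariff
  if (is.null(h$events))
    stop("accrual needs a history simulated with keep_events = TRUE")
  ev <- h$events
  ages <- numeric(0); costs <- numeric(0)
  chk <- ev[, "type"] %in% .mel_event_types[c("clinician_visit",
                                              "screening_round",
                                              "surveillance_visit")]
  if (any(chk)) {
    ch <- ev[chk, "channel"]
    base <- c(tf$check_cost$opportunistic_visit,
              tf$check_cost$routine_check,
              tf$check_cost$organised_screen,
              tf$check_cost$surveillance)[ch]
    # every skin check carries the keratinocyte/benign-lesion adjunct
    cost <- base + ec$keratinocyte_adjunct_cost
    cost <- cost + ifelse(ch == 3L, tf$program_per_invitee, 0)
    cost <- cost + ev[chk, "outcome"] * tf$false_positive_workup
    ages <- c(ages, ev[chk, "age"]); costs <- c(costs, cost)
  }
  dxe <- ev[, "type"] == .mel_event_types[["diagnosis"]]
  if (any(dxe)) {
    for (i in which(dxe)) {
      k <- ev[i, "tumour"]
      st <- h$tumours[[k]]$stage_at_diagnosis
      ages <- c(ages, ev[i, "age"])
      costs <- c(costs, tf$diagnostic_excision + tf$treatment_initial[[st]])
    }
  }
  list(ages = ages, costs = costs)
}

#' Accrue discounted costs, life years and QALYs on one life history
#'
#' Event costs (skin checks including the keratinocyte/benign adjunct,
#' false-positive workups, diagnostic excision and stage-specific initial
#' treatment at diagnosis, continuing stage-specific treatment over the
#' configured number of years) are discounted at their event times;
#' life years and QALYs are integrated continuously over state occupancy
#' with the utility weights, discounted at the same annual rate.
#'
#' @param history A `mel_history` simulated with `keep_events = TRUE`.
#' @param params A `mel_parameters` object (tariff, utilities, rate).
#' @param rate Annual discount rate; defaults to the economics block.
#' @param ref_age Reference age for discounting (default: cohort entry).
#' @return List with `cost`, `life_years`, `qalys` (discounted) and
#'   `undiscounted_life_years`, `undiscounted_qalys`.
#' @export
accrue <- function(history, params,
                   rate = params$economics$discount_rate,
                   ref_age = params$simulation$entry_age) {
  rho <- log(1 + rate)
  cr <- .cost_rows(history, params)
  cost <- sum(discount(cr$costs, pmax(cr$ages - ref_age, 0), rate))
  # continuing treatment: annual rate from diagnosis for a fixed horizon
  tf <- params$economics$tariff
  for (tm in history$tumours) {
    if (!isTRUE(tm$diagnosed)) next
    cont <- tf$treatment_continuing[[tm$stage_at_diagnosis]]
    if (cont <= 0) next
    a <- tm$diagnosis_age
    b <- min(a + tf$continuing_years, history$exit_age)
    cost <- cost + cont * .disc_integral(a, b, ref_age, rho)
  }
  seg <- .utility_segments(history, params)
  ea <- params$simulation$entry_age
  ly <- .disc_integral(ea, history$exit_age, ref_age, rho)
  qaly <- sum(vapply(seq_len(nrow(seg)), function(i)
    seg$w[i] * .disc_integral(seg$from[i], seg$to[i], ref_age, rho),
    numeric(1)))
  list(cost = cost, life_years = ly, qalys = qaly,
       undiscounted_life_years = history$exit_age - ea,
       undiscounted_qalys = sum(seg$w * (seg$to - seg$from)))
}

# Per-capita accrual means over a cohort.
.cohort_accrual <- function(cohort, params, rate) {
  acc <- lapply(cohort$histories, accrue, params = params, rate = rate)
  list(cost = mean(vapply(acc, `[[`, numeric(1), "cost")),
       life_years = mean(vapply(acc, `[[`, numeric(1), "life_years")),
       qalys = mean(vapply(acc, `[[`, numeric(1), "qalys")))
}

#' Compare two strategies (cost-effectiveness analysis)
#'
#' Per-capita discounted means under the strategy and the comparator
#' (both simulated with common random numbers on natural history),
#' incremental cost and effect, ICER per life year and per QALY, net
#' monetary benefit `NMB = wtp * dQALY - dCost`, and a dominance flag
#' when the increments have discordant favourable signs.
#'
#' @param strategy `mel_cohort` under the evaluated policy.
#' @param comparator `mel_cohort` under the comparator (e.g. the
#'   opportunistic, no-programme setting).
#' @param params A `mel_parameters` object.
#' @param rate Annual discount rate.
#' @param wtp Willingness-to-pay per QALY (default AUD 50,000).
#' @return List of class `mel_cea` (see fields in the description).
#' @export
compare_strategies <- function(strategy, comparator, params,
                               rate = params$economics$discount_rate,
                               wtp = params$economics$wtp_threshold) {
  if (strategy$n != comparator$n || strategy$seed != comparator$seed)
    stop("strategy and comparator must be paired cohorts ",
         "(same n and seed: common random numbers)")
  a <- .cohort_accrual(strategy, params, rate)
  b <- .cohort_accrual(comparator, params, rate)
  d_cost <- a$cost - b$cost
  d_ly <- a$life_years - b$life_years
  d_qaly <- a$qalys - b$qalys
  icer_ly <- if (abs(d_ly) > 0) d_cost / d_ly else NA_real_
  icer_qaly <- if (abs(d_qaly) > 0) d_cost / d_qaly else NA_real_
  nmb <- wtp * d_qaly - d_cost
  dominant <- (d_cost < 0 && d_qaly > 0) || (d_cost > 0 && d_qaly < 0)
  structure(list(strategy = a, comparator = b,
                 incremental_cost = d_cost, incremental_ly = d_ly,
                 incremental_qaly = d_qaly, icer_per_ly = icer_ly,
                 icer_per_qaly = icer_qaly, nmb = nmb,
                 icer_undefined = abs(d_qaly) == 0,
                 dominance = dominant, wtp = wtp,
                 cost_effective = nmb > 0),
            class = "mel_cea")
}

#' @export
print.mel_cea <- function(x, ...) {
  cat("<mel_cea> dCost", round(x$incremental_cost, 2), "| dQALY",
      signif(x$incremental_qaly, 4), "| ICER/QALY",
      if (is.na(x$icer_per_qaly)) "undefined"
      else round(x$icer_per_qaly), "| NMB", round(x$nmb, 2),
      if (x$cost_effective) "(cost-effective)" else "", "\n")
  invisible(x)
}

#' Overdiagnosis among screen-detected melanomas
#'
#' Counterfactual pairing under common random numbers: a screen-detected
#' tumour is overdiagnosed if, in the paired unscreened history of the
#' same individual, the same tumour is never clinically diagnosed before
#' exit (the individual dies of other causes or reaches the age cap
#' first). Because organised screening is gated to before the first
#' diagnosis, every screen-detected tumour is a first primary and is
#' shared between the paired arms.
#'
#' @param screened `mel_cohort` under the screening policy.
#' @param unscreened Paired `mel_cohort` (same seed and n) without it.
#' @return List with `proportion`, `n_screen_detected`,
#'   `n_overdiagnosed`.
#' @export
overdiagnosis_estimate <- function(screened, unscreened) {
  if (screened$n != unscreened$n || screened$seed != unscreened$seed)
    stop("cohorts must be paired by seed and n (common random numbers)")
  ids_u <- vapply(unscreened$histories, `[[`, numeric(1), "id")
  n_sd <- 0L; n_od <- 0L
  for (h in screened$histories) {
    for (tm in h$tumours) {
      if (!isTRUE(tm$diagnosed) ||
          !identical(tm$detect_channel, "organised_screen")) next
      n_sd <- n_sd + 1L
      hu <- unscreened$histories[[match(h$id, ids_u)]]
      counterfactual_dx <- FALSE
      if (length(hu$tumours) >= tm$tumour_index) {
        tu <- hu$tumours[[tm$tumour_index]]
        counterfactual_dx <- isTRUE(tu$diagnosed)
      }
      if (!counterfactual_dx) n_od <- n_od + 1L
    }
  }
  list(proportion = if (n_sd > 0) n_od / n_sd else NA_real_,
       n_screen_detected = n_sd, n_overdiagnosed = n_od)
}

#' Budget impact of a screening strategy
#'
#' Undiscounted incremental health-system cost per calendar year over a
#' short horizon (default five years), scaled from the simulated cohort
#' to a population of the given size. Continuing treatment costs are
#' allocated to calendar years by overlap. Programme fixed annual costs
#' are added in strategy years.
#'
#' @param strategy `mel_cohort` under the policy.
#' @param comparator Paired `mel_cohort` without it.
#' @param params A `mel_parameters` object.
#' @param population_size Population the cohort is scaled to.
#' @param start_year First calendar year of the horizon.
#' @param horizon Number of years (>= 1, default 5).
#' @return A `data.table` with one row per year: `year`,
#'   `incremental_cost`.
#' @export
budget_impact <- function(strategy, comparator, params, population_size,
                          start_year, horizon = 5) {
  if (horizon < 1) stop("horizon must be >= 1")
  if (strategy$n != comparator$n || strategy$seed != comparator$seed)
    stop("strategy and comparator must be paired cohorts")
  years <- start_year + seq_len(horizon) - 1L
  year_cost <- function(cohort) {
    tot <- numeric(horizon)
    tf <- params$economics$tariff
    for (h in cohort$histories) {
      cr <- .cost_rows(h, params)
      yr <- floor(h$birth_year + cr$ages)
      for (j in seq_len(horizon)) tot[j] <- tot[j] +
          sum(cr$costs[yr == years[j]])
      for (tm in h$tumours) {
        if (!isTRUE(tm$diagnosed)) next
        cont <- tf$treatment_continuing[[tm$stage_at_diagnosis]]
        if (cont <= 0) next
        a <- h$birth_year + tm$diagnosis_age
        b <- h$birth_year + min(tm$diagnosis_age + tf$continuing_years,
                                h$exit_age)
        for (j in seq_len(horizon)) {
          ov <- max(min(b, years[j] + 1) - max(a, years[j]), 0)
          tot[j] <- tot[j] + cont * ov
        }
      }
    }
    tot
  }
  scale <- population_size / strategy$n
  inc <- (year_cost(strategy) - year_cost(comparator)) * scale
  fixed <- params$economics$tariff$program_fixed_annual
  data.table::data.table(year = years,
                         incremental_cost = inc + fixed)
}

# ---- tariff / utility CSV interface -----------------------------------

.flatten_kv <- function(x, prefix = character(0)) {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- c(prefix, nm)
    if (is.list(v)) out <- c(out, .flatten_kv(v, key))
    else out[[paste(key, collapse = ".")]] <- as.numeric(v)
  }
  out
}

#' Read or write cost tariffs and utility weights as CSV
#'
#' Flat key-value CSV (`key`, `value`) with a schema line; keys are the
#' dotted paths within the economics block (e.g.
#' `tariff.check_cost.surveillance`, `utilities.IV`). Reading merges the
#' values into a parameter set's economics block and revalidates.
#'
#' @param params A `mel_parameters` object.
#' @param path CSV file path.
#' @return `write_econ_tables` returns `path`; `read_econ_tables`
#'   returns the updated parameter set.
#' @export
write_econ_tables <- function(params, path) {
  kv <- .flatten_kv(params$economics)
  df <- data.frame(key = names(kv), value = unlist(kv))
  .write_schema_csv(df, path, "melscreen-econ-1")
}

#' @rdname write_econ_tables
#' @export
read_econ_tables <- function(params, path) {
  df <- .read_schema_csv(path, "melscreen-econ-1")
  for (i in seq_len(nrow(df)))
    params <- param_set(params, paste0("economics.", df$key[i]),
                        df$value[i])
  rep <- validate_parameters(params)
  if (nrow(rep))
    stop("economics tables violate invariants:\n",
         paste0("  ", rep$path, ": ", rep$message, collapse = "\n"))
  params
}
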