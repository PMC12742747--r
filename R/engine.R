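# Continuous-time competing-risks engine. One individual's life history is
# advanced by exact inversion sampling of piecewise-constant hazards plus
# vectorised thinning of check processes; the earliest competing event wins.
# Natural-history channels (first emergence, tumour attributes, other-cause
# death, uptake) are consumed identically whatever the screening policy, so
# paired policy runs share the same underlying disease histories.

.mel_event_types <- c(
  skin_check_uptake = 1L, clinician_visit = 2L, screening_round = 3L,
  surveillance_visit = 4L, melanoma_emergence = 5L, diagnosis = 6L,
  melanoma_death = 7L, other_death = 8L, age_cap_exit = 9L
)
.mel_check_channels <- c(opportunistic_visit = 1L, routine_check = 2L,
                         organised_screen = 3L, surveillance = 4L)

# Vectorised per-check detection probability (channel-coded).
.det_prob_vec <- function(histology, dwell, year, visible, chcode, policy,
                          params) {
  cv <- params$detection$curves[[histology]]
  p <- cv$pmax - (cv$pmax - cv$p0) * exp(-cv$rate * dwell)
  vis <- if (visible) 1 else params$detection$visibility_less_factor
  per <- .calendar_ramp(year, params$detection$period)
  sens <- ifelse(chcode == .mel_check_channels[["organised_screen"]],
                 if (is.null(policy)) 1 else policy$sensitivity, 1)
  pmin(pmax(p * vis * per * sens, 0), 1)
}

.fp_prob_vec <- function(chcode, policy, params) {
  sp <- params$detection$specificity
  spec <- numeric(length(chcode))
  spec[chcode == 1L] <- sp$opportunistic_visit
  spec[chcode == 2L] <- sp$routine_check
  spec[chcode == 3L] <- if (is.null(policy)) 1 else policy$specificity
  spec[chcode == 4L] <- sp$surveillance
  1 - spec
}

# Opportunistic visit times on [a, b) by thinning; symptom boost applies
# after emergence age E (may be Inf), scaled by the tumour's progression
# when its histology is known.
.gen_visits <- function(a, b, sex, E, stream, params, histology = NULL) {
  if (b <= a) return(numeric(0))
  vr <- params$visit_rates
  sf <- if (sex == "female") vr$female_factor else 1
  lmax <- max(vr$rates) * sf
  if (is.finite(E) && E < b) lmax <- lmax * (1 + vr$emergence_boost)
  if (lmax <= 0) return(numeric(0))
  n <- stats::qpois(stream_uniform(stream, "visits", 1L), lmax * (b - a))
  if (n == 0L) return(numeric(0))
  t <- a + sort(stream_uniform(stream, "visits", n)) * (b - a)
  ua <- stream_uniform(stream, "visits", n)
  tse <- ifelse(t > E, t - E, NA_real_)
  lam <- visit_hazard(t, sex, "average", tse, params,
                      histology = histology)
  t[ua * lmax <= lam]
}

#' Simulate one individual's life history
#'
#' Runs the full discrete-event simulation for one individual: other-cause
#' death and first-primary emergence are pre-sampled by hazard inversion;
#' skin-check processes (opportunistic visits, routine checks after
#' uptake, organised rounds, post-diagnosis surveillance) generate
#' detection opportunities; diagnosis fixes stage via the dwell-time stage
#' schedules; melanoma-specific death competes from the diagnosed state.
#' Exit is absorbing at the earliest of other-cause death, melanoma death
#' and the age cap.
#'
#' @param params A validated `mel_parameters` object.
#' @param attributes List with `sex` (`"male"`/`"female"`), `birth_year`
#'   (real) and `risk_group` (label).
#' @param policy A `mel_policy` or `NULL` (opportunistic setting only).
#' @param stream A `mel_stream` for this individual.
#' @param keep_events Keep the full event log (set `FALSE` for large
#'   cohorts where only tumours and exit are needed).
#' @return A list of class `mel_history` with `id`, `sex`, `birth_year`,
#'   `risk_group`, `events` (matrix: age, type, channel, outcome,
#'   tumour), `tumours` (list), `exit_age`, `exit_cause`.
#' @export
simulate_individual <- function(params, attributes, policy = NULL,
                                stream, keep_events = TRUE) {
  ea <- params$simulation$entry_age
  ma <- params$simulation$max_age
  sex <- attributes$sex
  by <- attributes$birth_year
  rg <- .risk_group(params, attributes$risk_group)

  # natural-history pre-samples (policy-invariant channels)
  T_od <- pc_invert(.other_cause_pc(params, sex), ea,
                    -log(stream_uniform(stream, "other_death", 1L)))
  E1 <- pc_invert(.first_primary_pc(params, sex, by, rg), ea,
                  -log(stream_uniform(stream, "emergence", 1L)))
  U <- pc_invert(.uptake_pc(params, sex, by, rg), ea,
                 -log(stream_uniform(stream, "uptake", 1L)))
  horizon0 <- min(T_od, ma)

  ev_age <- numeric(0); ev_type <- integer(0); ev_ch <- integer(0)
  ev_out <- integer(0); ev_tum <- integer(0)
  add_ev <- function(age, type, ch = 0L, out = 0L, tum = 0L) {
    ev_age <<- c(ev_age, age); ev_type <<- c(ev_type, type)
    ev_ch <<- c(ev_ch, ch); ev_out <<- c(ev_out, out)
    ev_tum <<- c(ev_tum, tum)
  }
  tumours <- list()

  # ---- pre-first-diagnosis phase --------------------------------------
  tum1 <- NULL
  if (E1 < horizon0) {
    hist1 <- assign_histology(E1, stream, params)
    site1 <- .assign_body_site(stream, params)
    tum1 <- list(tumour_index = 1L, histology = hist1,
                 emergence_age = E1, body_site = site1$code,
                 body_site_visible = site1$visible, diagnosed = FALSE,
                 diagnosis_age = NA_real_, dwell_at_diagnosis = NA_real_,
                 stage_at_diagnosis = NA_character_,
                 breslow_category = NA_character_,
                 behaviour_code = NA_integer_,
                 detect_channel = NA_character_)
  } else {
    E1 <- Inf
  }

  vt <- .gen_visits(ea, horizon0, sex, E1, stream, params,
                    histology = if (is.null(tum1)) NULL else
                      tum1$histology)
  ct <- rep.int(1L, length(vt))

  if (U < horizon0) {
    rt <- seq(U, horizon0, by = params$routine_interval)
    ua <- stream_uniform(stream, "routine", length(rt))
    rt <- rt[ua < attendance_probability(rt - U, params)]
    vt <- c(vt, rt); ct <- c(ct, rep.int(2L, length(rt)))
  }

  eligible <- !is.null(policy) &&
    (is.null(policy$risk_groups) || rg$label %in% policy$risk_groups)
  if (eligible) {
    ot <- .organised_round_ages(policy, by, params)
    ot <- ot[ot < horizon0]
    if (length(ot)) {
      up <- stream_uniform(stream, "screening", length(ot))
      ot <- ot[up < policy$participation]
      vt <- c(vt, ot); ct <- c(ct, rep.int(3L, length(ot)))
    }
  }

  ord <- order(vt)
  vt <- vt[ord]; ct <- ct[ord]
  nck <- length(vt)
  dx1_age <- Inf; dx1_ch <- NA_integer_
  fp_flag <- logical(nck)
  if (nck) {
    u <- stream_uniform(stream, "detection", nck)
    post <- vt >= E1
    pdet <- numeric(nck)
    if (any(post))
      pdet[post] <- .det_prob_vec(tum1$histology, vt[post] - E1,
                                  by + vt[post], tum1$body_site_visible,
                                  ct[post], policy, params)
    hit <- post & (u < pdet)
    i1 <- which(hit)
    if (length(i1)) {
      dx1_age <- vt[i1[1L]]
      dx1_ch <- ct[i1[1L]]
    }
    pfp <- .fp_prob_vec(ct, policy, params)
    fp_flag <- !post & (u < pfp)
  }

  keep <- vt <= dx1_age
  vt <- vt[keep]; ct <- ct[keep]; fp_flag <- fp_flag[keep]

  if (keep_events) {
    if (U < min(horizon0, dx1_age))
      add_ev(U, .mel_event_types[["skin_check_uptake"]])
    if (length(vt)) {
      etype <- ifelse(ct == 3L, .mel_event_types[["screening_round"]],
                      .mel_event_types[["clinician_visit"]])
      ev_age <- c(ev_age, vt); ev_type <- c(ev_type, etype)
      ev_ch <- c(ev_ch, ct); ev_out <- c(ev_out, as.integer(fp_flag))
      ev_tum <- c(ev_tum, integer(length(vt)))
    }
  }
  n_fp <- sum(fp_flag)

  exit_age <- horizon0
  exit_cause <- if (T_od <= ma) "other_death" else "age_cap"

  if (!is.null(tum1)) {
    if (keep_events)
      add_ev(E1, .mel_event_types[["melanoma_emergence"]], tum = 1L)
    tumours[[1L]] <- tum1
  }

  if (is.finite(dx1_age)) {
    stg <- stage_at_diagnosis(tum1$histology, dx1_age - E1, params)
    tumours[[1L]]$diagnosed <- TRUE
    tumours[[1L]]$diagnosis_age <- dx1_age
    tumours[[1L]]$dwell_at_diagnosis <- dx1_age - E1
    tumours[[1L]]$stage_at_diagnosis <- stg$stage
    tumours[[1L]]$breslow_category <- stg$breslow_category
    tumours[[1L]]$behaviour_code <- stg$behaviour_code
    tumours[[1L]]$detect_channel <-
      names(.mel_check_channels)[dx1_ch]
    if (keep_events)
      add_ev(dx1_age, .mel_event_types[["diagnosis"]], ch = dx1_ch,
             tum = 1L)

    # ---- post-diagnosis phases ----------------------------------------
    stage1 <- stg$stage
    hist1 <- tum1$histology
    sched <- surveillance_schedule(stage1, rg, params,
                                   diagnosis_age = dx1_age)
    surv_ages <- dx1_age + sched
    cur <- dx1_age
    n_dx <- 1L
    repeat {
      dpc <- .total_death_pc(tumours, params, cur)
      T_md <- if (is.null(dpc)) Inf else
        pc_invert(dpc, cur, -log(stream_uniform(stream, "melanoma_death",
                                                1L)))
      horiz <- min(T_od, T_md, ma)
      E_next <- pc_invert(
        .subsequent_pc(params, sex, by, rg, hist1, n_dx), cur,
        -log(stream_uniform(stream, "emergence", 1L)))
      tum_next <- NULL
      if (E_next < horiz) {
        hn <- assign_subsequent_histology(hist1, E_next, stream, params)
        sn <- .assign_body_site(stream, params)
        tum_next <- list(tumour_index = n_dx + 1L, histology = hn,
                         emergence_age = E_next, body_site = sn$code,
                         body_site_visible = sn$visible, diagnosed = FALSE,
                         diagnosis_age = NA_real_,
                         dwell_at_diagnosis = NA_real_,
                         stage_at_diagnosis = NA_character_,
                         breslow_category = NA_character_,
                         behaviour_code = NA_integer_,
                         detect_channel = NA_character_)
      } else E_next <- Inf

      st <- surv_ages[surv_ages > cur & surv_ages < horiz]
      if (length(st)) {
        us <- stream_uniform(stream, "surveillance", length(st))
        st <- st[us < .surveillance_attendance(st - dx1_age, stage1,
                                               hist1, params)]
      }
      pv <- .gen_visits(cur, horiz, sex, E_next, stream, params,
                        histology = if (is.null(tum_next)) NULL else
                          tum_next$histology)
      wt <- c(st, pv)
      wc <- c(rep.int(4L, length(st)), rep.int(1L, length(pv)))
      ordw <- order(wt)
      wt <- wt[ordw]; wc <- wc[ordw]
      nw <- length(wt)
      dxn_age <- Inf; dxn_ch <- NA_integer_
      fpw <- logical(nw)
      if (nw) {
        uw <- stream_uniform(stream, "detection", nw)
        postw <- wt >= E_next
        pd <- numeric(nw)
        if (any(postw))
          pd[postw] <- .det_prob_vec(tum_next$histology, wt[postw] - E_next,
                                     by + wt[postw],
                                     tum_next$body_site_visible,
                                     wc[postw], policy, params)
        hitw <- postw & (uw < pd)
        iw <- which(hitw)
        if (length(iw)) { dxn_age <- wt[iw[1L]]; dxn_ch <- wc[iw[1L]] }
        fpw <- !postw & (uw < .fp_prob_vec(wc, policy, params))
      }
      keepw <- wt <= dxn_age
      wt <- wt[keepw]; wc <- wc[keepw]; fpw <- fpw[keepw]
      if (keep_events && length(wt)) {
        etype <- ifelse(wc == 4L, .mel_event_types[["surveillance_visit"]],
                        .mel_event_types[["clinician_visit"]])
        ev_age <- c(ev_age, wt); ev_type <- c(ev_type, etype)
        ev_ch <- c(ev_ch, wc); ev_out <- c(ev_out, as.integer(fpw))
        ev_tum <- c(ev_tum, integer(length(wt)))
      }
      n_fp <- n_fp + sum(fpw)

      if (!is.null(tum_next) && E_next < min(dxn_age, horiz)) {
        if (keep_events)
          add_ev(E_next, .mel_event_types[["melanoma_emergence"]],
                 tum = tum_next$tumour_index)
        tumours[[tum_next$tumour_index]] <- tum_next
      }

      if (is.finite(dxn_age)) {
        stgn <- stage_at_diagnosis(tum_next$histology, dxn_age - E_next,
                                   params)
        k <- tum_next$tumour_index
        tumours[[k]]$diagnosed <- TRUE
        tumours[[k]]$diagnosis_age <- dxn_age
        tumours[[k]]$dwell_at_diagnosis <- dxn_age - E_next
        tumours[[k]]$stage_at_diagnosis <- stgn$stage
        tumours[[k]]$breslow_category <- stgn$breslow_category
        tumours[[k]]$behaviour_code <- stgn$behaviour_code
        tumours[[k]]$detect_channel <- names(.mel_check_channels)[dxn_ch]
        if (keep_events)
          add_ev(dxn_age, .mel_event_types[["diagnosis"]], ch = dxn_ch,
                 tum = k)
        cur <- dxn_age
        n_dx <- n_dx + 1L
        next
      }

      exit_age <- horiz
      exit_cause <- if (horiz == T_od && T_od <= min(T_md, ma))
        "other_death"
      else if (horiz == T_md) "melanoma_death" else "age_cap"
      break
    }
  }

  if (keep_events) {
    etype_exit <- switch(exit_cause,
                         other_death = .mel_event_types[["other_death"]],
                         melanoma_death = .mel_event_types[["melanoma_death"]],
                         age_cap = .mel_event_types[["age_cap_exit"]])
    add_ev(exit_age, etype_exit)
    ord <- order(ev_age, .mel_event_prio_of(ev_type))
    events <- cbind(age = ev_age[ord], type = ev_type[ord],
                    channel = ev_ch[ord], outcome = ev_out[ord],
                    tumour = ev_tum[ord])
  } else {
    events <- NULL
  }

  structure(list(id = stream$id, sex = sex, birth_year = by,
                 risk_group = rg$label, events = events,
                 tumours = tumours, n_false_positives = n_fp,
                 exit_age = exit_age, exit_cause = exit_cause),
            class = "mel_history")
}

# priority rank of event-type codes for within-age ordering
.mel_event_prio_of <- function(type_codes) {
  nm <- names(.mel_event_types)[type_codes]
  pr <- .mel_event_priority[nm]
  pr[is.na(pr)] <- 50L
  pr
}

#' @export
print.mel_history <- function(x, ...) {
  cat("<mel_history> id", x$id, x$sex, "b.", round(x$birth_year, 1),
      "| risk", x$risk_group, "|", length(x$tumours), "tumour(s) | exit",
      round(x$exit_age, 2), paste0("(", x$exit_cause, ")"), "\n")
  invisible(x)
}

# Cohort attribute assignment for one id (attrs channel: 3 draws).
.draw_attributes <- function(params, stream) {
  u <- stream_uniform(stream, "attrs", 3L)
  dem <- params$demographics
  sex <- if (u[1L] < dem$prop_female) "female" else "male"
  by <- dem$birth_year_min + u[2L] * (dem$birth_year_max -
                                        dem$birth_year_min)
  fr <- cumsum(vapply(params$risk_groups, `[[`, numeric(1), "fraction"))
  rgi <- findInterval(u[3L], fr) + 1L
  rgi <- min(rgi, length(params$risk_groups))
  list(sex = sex, birth_year = by,
       risk_group = params$risk_groups[[rgi]]$label)
}

#' Simulate a cohort
#'
#' Simulates `n` individuals with independent per-individual substreams
#' derived from `seed`, so results are reproducible and invariant to
#' execution order: a cohort split into two halves with the same seed is
#' identical to the single run.
#'
#' @param params A validated `mel_parameters` object.
#' @param n Number of individuals (>= 1).
#' @param seed Integer root seed.
#' @param policy A `mel_policy` or `NULL`.
#' @param keep_events Keep full per-individual event logs.
#' @param ids Integer ids to simulate (default `1:n`); ids determine the
#'   substreams, enabling split/merge runs.
#' @return Object of class `mel_cohort`: list of histories plus metadata.
#' @export
simulate_cohort <- function(params, n, seed, policy = NULL,
                            keep_events = TRUE, ids = seq_len(n)) {
  if (n < 1) stop("n must be >= 1")
  rep <- validate_parameters(params)
  if (nrow(rep))
    stop("invalid parameter set; see validate_parameters()")
  histories <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    stream <- random_stream(seed, ids[j])
    attrs <- .draw_attributes(params, stream)
    histories[[j]] <- simulate_individual(params, attrs, policy, stream,
                                          keep_events = keep_events)
  }
  structure(list(histories = histories, n = length(ids), seed = seed,
                 policy = policy, entry_age = params$simulation$entry_age,
                 max_age = params$simulation$max_age),
            class = "mel_cohort")
}

#' @export
print.mel_cohort <- function(x, ...) {
  ndx <- sum(vapply(x$histories, function(h)
    any(vapply(h$tumours, function(t) isTRUE(t$diagnosed), logical(1))),
    logical(1)))
  cat("<mel_cohort> n =", x$n, "| seed", x$seed, "|", ndx,
      "individuals with >= 1 diagnosis\n")
  invisible(x)
}

#' Event log of a cohort as a table
#'
#' One row per recorded event: individual id, event type, exact age,
#' calendar year (floored), detection channel, outcome flag (1 = false
#' positive for check events) and tumour index.
#'
#' @param cohort A `mel_cohort` simulated with `keep_events = TRUE`.
#' @return A `data.table`.
#' @export
events_table <- function(cohort) {
  tabs <- lapply(cohort$histories, function(h) {
    if (is.null(h$events) || nrow(h$events) == 0L) return(NULL)
    chidx <- h$events[, "channel"]
    chidx[chidx < 1] <- NA  # 0 marks non-check events; NA index -> NA
    data.table::data.table(
      individual_id = h$id,
      event = names(.mel_event_types)[h$events[, "type"]],
      age = h$events[, "age"],
      calendar_year = floor(h$birth_year + h$events[, "age"]),
      channel = names(.mel_check_channels)[chidx],
      outcome = h$events[, "outcome"],
      tumour_index = h$events[, "tumour"])
  })
  data.table::rbindlist(tabs)
}

#' Tumour table of a cohort
#'
#' One row per tumour (diagnosed or not) with ICD-O-3 topography
#' (C44.0-C44.9), morphology band label (M872-M879 family) and behaviour
#' code 2 (in situ) / 3 (invasive) for diagnosed tumours.
#'
#' @param cohort A `mel_cohort`.
#' @return A `data.table`.
#' @export
tumours_table <- function(cohort) {
  tabs <- lapply(cohort$histories, function(h) {
    if (!length(h$tumours)) return(NULL)
    data.table::rbindlist(lapply(h$tumours, function(tm) {
      data.table::data.table(
        individual_id = h$id, sex = h$sex,
        birth_year = h$birth_year, risk_group = h$risk_group,
        tumour_index = tm$tumour_index, histology = tm$histology,
        morphology = unname(.mel_morphology[tm$histology]),
        topography = tm$body_site,
        emergence_age = tm$emergence_age, diagnosed = tm$diagnosed,
        diagnosis_age = tm$diagnosis_age,
        dwell_at_diagnosis = tm$dwell_at_diagnosis,
        stage_at_diagnosis = tm$stage_at_diagnosis,
        breslow_category = tm$breslow_category,
        behaviour_code = tm$behaviour_code,
        detect_channel = tm$detect_channel,
        exit_age = h$exit_age, exit_cause = h$exit_cause)
    }))
  })
  out <- data.table::rbindlist(tabs)
  if (!nrow(out)) return(out)
  out
}

# Per-individual exit summary (always available, even without events).
.exit_table <- function(cohort) {
  data.table::rbindlist(lapply(cohort$histories, function(h)
    data.table::data.table(individual_id = h$id, sex = h$sex,
                           birth_year = h$birth_year,
                           risk_group = h$risk_group,
                           exit_age = h$exit_age,
                           exit_cause = h$exit_cause,
                           n_false_positives = h$n_false_positives)))
}
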