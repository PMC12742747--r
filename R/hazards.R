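#' Piecewise-constant hazard
#'
#' Constructs a hazard that is constant on half-open age intervals
#' `[breaks[i], breaks[i+1])`. The last break may be `Inf`. All rates are
#' per person-year; the hazard is zero outside `[breaks[1], breaks[k+1])`.
#'
#' @param breaks Strictly increasing numeric vector of interval endpoints
#'   (length one more than `rates`).
#' @param rates Non-negative rates, one per interval.
#' @return An object of class `pc_hazard`.
#' @export
#' @examples
#' h <- pc_hazard(c(15, 50, Inf), c(0.01, 0.02))
pc_hazard <- function(breaks, rates) {
  breaks <- as.numeric(breaks)
  rates <- as.numeric(rates)
  if (length(breaks) != length(rates) + 1L)
    stop("`breaks` must have length(rates) + 1 entries")
  if (any(diff(breaks) <= 0)) stop("`breaks` must be strictly increasing")
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("hazard rates must be finite and >= 0")
  structure(list(breaks = breaks, rates = rates), class = "pc_hazard")
}

#' @export
print.pc_hazard <- function(x, ...) {
  cat("<pc_hazard> ", length(x$rates), " segments on [",
      x$breaks[1], ", ", x$breaks[length(x$breaks)], ")\n", sep = "")
  invisible(x)
}

# Evaluate the hazard at ages (vectorised).
pc_rate <- function(haz, age) {
  idx <- findInterval(age, haz$breaks, rightmost.closed = FALSE)
  out <- numeric(length(age))
  ok <- idx >= 1L & idx <= length(haz$rates)
  out[ok] <- haz$rates[idx[ok]]
  out
}

# Cumulative hazard from `from` to `to` (scalars or vectors of equal length).
pc_cumhaz <- function(haz, from, to) {
  b <- haz$breaks
  r <- haz$rates
  k <- length(r)
  n <- max(length(from), length(to))
  from <- rep_len(from, n)
  to <- rep_len(to, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- pmin(pmax(b[-(k + 1L)], from[i]), to[i])
    hi <- pmin(pmax(b[-1L], from[i]), to[i])
    w <- hi - lo
    w[w < 0] <- 0
    # Inf segment with zero rate contributes 0, not NaN
    contrib <- ifelse(w > 0, w * r, 0)
    out[i] <- sum(contrib)
  }
  out
}

# Invert the cumulative hazard: smallest t > start with H(start, t) = target.
# Returns Inf when the total available hazard is exhausted first.
pc_invert <- function(haz, start, target) {
  b <- haz$breaks
  r <- haz$rates
  k <- length(r)
  if (target <= 0) return(start)
  acc <- 0
  for (i in seq_len(k)) {
    lo <- max(b[i], start)
    hi <- b[i + 1L]
    if (hi <= lo) next
    if (r[i] <= 0) next
    seg <- if (is.finite(hi)) (hi - lo) * r[i] else Inf
    if (acc + seg >= target) return(lo + (target - acc) / r[i])
    acc <- acc + seg
  }
  Inf
}

#' Sample an event time from a piecewise-constant hazard
#'
#' Exact inversion sampling: with `U ~ U(0,1)` the sampled age solves
#' `H(start_age, t) = -log(U)` where `H` is the cumulative hazard. When the
#' hazard remaining after `start_age` is finite and exhausted before the
#' target, the event never happens and `Inf` is returned.
#'
#' @param hazard A [pc_hazard()].
#' @param start_age Age (years) at which the clock starts.
#' @param stream Optional `mel_stream`; if supplied, one deviate is drawn
#'   from `channel`. Otherwise `u` must be given.
#' @param channel Stream channel name (see [stream_uniform()]).
#' @param u Optional uniform deviate in (0,1), used instead of `stream`.
#' @return Sampled age (`> start_age`), or `Inf` for "never".
#' @export
sample_event_time <- function(hazard, start_age, stream = NULL,
                              channel = "emergence", u = NULL) {
  stopifnot(inherits(hazard, "pc_hazard"))
  if (is.null(u)) {
    if (is.null(stream)) stop("supply either `stream` or `u`")
    u <- stream_uniform(stream, channel, 1L)
  }
  pc_invert(hazard, start_age, -log(u))
}

# Absorbing-first tie priority: a same-instant diagnosis never post-dates
# death.
.mel_event_priority <- c(
  other_death = 1L, melanoma_death = 2L, diagnosis = 3L,
  melanoma_emergence = 4L, surveillance_visit = 5L, screening_round = 6L,
  clinician_visit = 7L, skin_check_uptake = 8L, age_cap_exit = 9L
)

#' Select the earliest of a set of competing events
#'
#' Returns the candidate with the smallest age; exact ties are broken by a
#' fixed priority (`other_death` > `melanoma_death` > `diagnosis` >
#' `melanoma_emergence` > `surveillance_visit` > `screening_round` >
#' `clinician_visit` > `skin_check_uptake`).
#'
#' @param candidates A non-empty list of events, each a list with at least
#'   `type` (character) and `age` (numeric).
#' @return The winning event (one element of `candidates`).
#' @export
resolve_competing <- function(candidates) {
  if (!is.list(candidates) || length(candidates) == 0L)
    stop("`candidates` must be a non-empty list of events")
  ages <- vapply(candidates, function(e) as.numeric(e$age), numeric(1))
  types <- vapply(candidates, function(e) as.character(e$type), character(1))
  prio <- .mel_event_priority[types]
  prio[is.na(prio)] <- 99L
  ord <- order(ages, prio)
  candidates[[ord[1L]]]
}
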