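# Mortality: melanoma-specific death hazards after diagnosis (stage and
# Breslow dependent, piecewise-constant in time-since-diagnosis bands,
# summed over all diagnosed invasive primaries) and other-cause mortality
# from a life table. Melanoma-specific death requires prior diagnosis; an
# undiagnosed tumour instead keeps progressing, so a late diagnosis
# carries a high death hazard.

#' Melanoma-specific death hazard of one diagnosed tumour
#'
#' Piecewise-constant in time-since-diagnosis bands (0-1, 1-5, 5+ years
#' by default), indexed by stage at diagnosis and — within stages I-II —
#' the Breslow thickness category. In situ tumours confer no
#' melanoma-specific death hazard.
#'
#' @param tumour List with `stage_at_diagnosis`, `breslow_category`,
#'   `behaviour_code`, and `diagnosed` flag (or any object with those
#'   fields).
#' @param time_since_diagnosis Years since this tumour's diagnosis.
#' @param age Attained age (not used by the default profiles; kept in the
#'   signature for parameterisations that add age modification).
#' @param params A `mel_parameters` object.
#' @return Rate per person-year.
#' @export
melanoma_death_hazard <- function(tumour, time_since_diagnosis, age = NA,
                                  params) {
  if (!isTRUE(tumour$diagnosed))
    stop("melanoma death hazard is only defined after diagnosis")
  if (tumour$behaviour_code == 2L || tumour$stage_at_diagnosis == "in_situ")
    return(rep(0, length(time_since_diagnosis)))
  sv <- params$survival
  hz <- sv$hazards[[tumour$stage_at_diagnosis]]
  vec <- if (!is.null(hz$any)) hz$any else hz[[tumour$breslow_category]]
  band <- pmin(pmax(findInterval(time_since_diagnosis, sv$time_breaks), 1L),
               length(vec))
  vec[band]
}

# Per-tumour survival hazard vector and its pc_hazard in *age* for a
# tumour diagnosed at dx_age.
.tumour_death_pc <- function(tumour, dx_age, params, max_age) {
  sv <- params$survival
  hz <- sv$hazards[[tumour$stage_at_diagnosis]]
  vec <- if (!is.null(hz$any)) hz$any else hz[[tumour$breslow_category]]
  breaks <- c(dx_age + sv$time_breaks, Inf)
  pc_hazard(breaks, vec)
}

#' Total melanoma-specific death hazard of an individual
#'
#' Sum of the per-tumour hazards over all diagnosed invasive tumours;
#' zero when there are none. The number of melanomas enters only through
#' this sum — there is no count-dependent term, so more primaries do not
#' by themselves force worse survival.
#'
#' @param tumours List of tumour records (each with `diagnosed`,
#'   `behaviour_code`, `stage_at_diagnosis`, `breslow_category`,
#'   `diagnosis_age`).
#' @param age Attained age (years).
#' @param params A `mel_parameters` object.
#' @return Rate per person-year.
#' @export
total_melanoma_death_hazard <- function(tumours, age, params) {
  total <- 0
  for (tum in tumours) {
    if (!isTRUE(tum$diagnosed) || tum$behaviour_code != 3L) next
    total <- total +
      melanoma_death_hazard(tum, age - tum$diagnosis_age, age, params)
  }
  total
}

# Combined pc_hazard in age over all diagnosed invasive tumours, for
# inversion sampling from `from_age`.
.total_death_pc <- function(tumours, params, from_age) {
  ma <- params$simulation$max_age
  segs <- list()
  for (tum in tumours) {
    if (!isTRUE(tum$diagnosed) || tum$behaviour_code != 3L) next
    segs[[length(segs) + 1L]] <- .tumour_death_pc(tum, tum$diagnosis_age,
                                                  params, ma)
  }
  if (!length(segs)) return(NULL)
  brk <- sort(unique(c(from_age, unlist(lapply(segs, `[[`, "breaks")))))
  brk <- brk[brk >= from_age & is.finite(brk)]
  brk <- c(brk, Inf)
  mid <- utils::head(brk, -1L) + pmin(diff(brk), 1) / 2
  rates <- Reduce(`+`, lapply(segs, function(h) pc_rate(h, mid)))
  pc_hazard(brk, rates)
}

#' Other-cause mortality hazard from a life table
#'
#' @param age Age(s) in years, within the table range.
#' @param sex `"male"` or `"female"`.
#' @param life_table A life-table list (`age_breaks`, `male`, `female`)
#'   such as `params$life_table`, or a data frame read by
#'   [read_life_table()].
#' @return Annual rate(s).
#' @export
other_cause_hazard <- function(age, sex, life_table) {
  if (is.data.frame(life_table)) life_table <- .lt_from_df(life_table)
  brk <- life_table$age_breaks
  if (any(age < brk[1]) || any(age >= brk[length(brk)]))
    stop("age outside life-table range")
  r <- if (sex == "female") life_table$female else life_table$male
  r[findInterval(age, brk)]
}

.other_cause_pc <- function(params, sex) {
  lt <- params$life_table
  r <- if (sex == "female") lt$female else lt$male
  pc_hazard(lt$age_breaks, r)
}

# ---- life-table CSV interface -----------------------------------------

.lt_from_df <- function(df) {
  df <- df[order(df$sex, df$age_low), ]
  m <- df[df$sex == "male", ]
  f <- df[df$sex == "female", ]
  if (!identical(m$age_low, f$age_low))
    stop("life table must have matching male/female age bands")
  if (any(m$age_low[-1] != m$age_high[-nrow(m)]))
    stop("life-table age bands must be contiguous")
  list(age_breaks = c(m$age_low, m$age_high[nrow(m)]),
       male = m$rate, female = f$rate)
}

#' Read or write a life table as CSV
#'
#' Columns: `age_low`, `age_high`, `sex` (`male`/`female`), `rate`
#' (annual other-cause mortality). The first line declares the schema
#' (`#schema=melscreen-lifetable-1`) and is rejected if unknown.
#'
#' @param path CSV file path.
#' @return `read_life_table` returns a life-table list with
#'   `age_breaks`, `male`, `female`; `write_life_table` returns `path`.
#' @export
read_life_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, "#schema=melscreen-lifetable-1"))
    stop("unknown life-table schema: ", first)
  df <- utils::read.csv(path, comment.char = "#")
  if (any(df$rate < 0)) stop("life-table rates must be >= 0")
  .lt_from_df(df)
}

#' @rdname read_life_table
#' @param life_table Life-table list (`age_breaks`, `male`, `female`).
#' @export
write_life_table <- function(life_table, path) {
  brk <- life_table$age_breaks
  n <- length(brk) - 1L
  df <- data.frame(
    age_low = rep(brk[-length(brk)], 2L),
    age_high = rep(brk[-1L], 2L),
    sex = rep(c("male", "female"), each = n),
    rate = c(life_table$male, life_table$female))
  writeLines("#schema=melscreen-lifetable-1", path)
  suppressWarnings(utils::write.table(
    df, path, sep = ",", row.names = FALSE, col.names = TRUE,
    append = TRUE, quote = FALSE))
  invisible(path)
}
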