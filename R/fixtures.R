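# Synthetic fixture bundles and file output. No real registry, Medicare or
# survey data is used anywhere: the bundle's calibration targets are
# produced by simulating the bundled parameter set itself, so calibration
# tests have a known generating truth.

.mel_scenarios <- c("australia_like", "high_risk_stress")

#' Generate a self-consistent synthetic fixture bundle
#'
#' Returns the parameter set for a named scenario together with its life
#' table, a registry-style table of calibration targets computed by
#' simulating that very parameter set (so the bundle is self-consistent:
#' re-simulating at the bundled parameters with the same seed gives
#' distance 0 up to the target noise), and the cost/utility blocks.
#'
#' Scenarios: `"australia_like"` (the packaged default: Australian-like
#' age/sex/birth-cohort incidence, histology mix, and a second-primary
#' frequency matching the ~16% 10-year national proportion) and
#' `"high_risk_stress"` (emergence hazards scaled up so multi-primary
#' histories are common; used to exercise the no-tumour-cap property).
#'
#' @param scenario Scenario name.
#' @param seed Integer seed for the target-generating simulation.
#' @param n_target_sim Cohort size behind the synthetic targets.
#' @return List with `params`, `life_table`, `targets`, `tariff`,
#'   `utilities`, `scenario`, `seed`.
#' @export
generate_fixture_bundle <- function(scenario = "australia_like", seed = 1L,
                                    n_target_sim = 4000L) {
  if (!scenario %in% .mel_scenarios)
    stop("unknown scenario '", scenario, "'; available: ",
         paste(.mel_scenarios, collapse = ", "))
  params <- default_parameters()
  if (scenario == "high_risk_stress") {
    params$baseline_incidence$scale <- 25
    params$post_diagnosis_risk_multipliers <- c(20, 30, 40, 50)
  }
  strata <- summary_strata()
  cohort <- simulate_cohort(params, n_target_sim, seed,
                            keep_events = FALSE)
  sm <- compute_summaries(cohort, strata)
  targets <- sm[!is.na(sm$value), ]
  targets$weight <- 1
  list(params = params, life_table = params$life_table,
       targets = targets, tariff = params$economics$tariff,
       utilities = params$economics$utilities,
       scenario = scenario, seed = seed)
}

# ---- versioned CSV helpers --------------------------------------------

.write_schema_csv <- function(df, path, schema) {
  writeLines(paste0("#schema=", schema), path)
  suppressWarnings(utils::write.table(
    df, path, sep = ",", row.names = FALSE, col.names = TRUE,
    append = TRUE, quote = FALSE, na = ""))
  invisible(path)
}

.read_schema_csv <- function(path, schema) {
  first <- readLines(path, n = 1L)
  if (!identical(first, paste0("#schema=", schema)))
    stop("unknown schema in ", path, ": ", first,
         " (expected #schema=", schema, ")")
  utils::read.csv(path, comment.char = "#", na.strings = "")
}

#' Read or write a calibration-target table as CSV
#'
#' Columns: `statistic`, `sex`, `age_low`, `age_high`, `value`, `weight`;
#' missing values are empty fields. The first line declares the schema
#' and unknown schemas are rejected.
#'
#' @param targets Target table.
#' @param path CSV path.
#' @return The table (read) or `path` (write).
#' @export
write_targets <- function(targets, path)
  .write_schema_csv(targets, path, "melscreen-targets-1")

#' @rdname write_targets
#' @export
read_targets <- function(path)
  .read_schema_csv(path, "melscreen-targets-1")

#' Write cohort outputs to a destination directory
#'
#' Writes `events.csv` (one line per event), `tumours.csv` (one line per
#' tumour, with ICD-O-3 topography, morphology band labels, and
#' behaviour code 2/3), `summary.csv` (registry-style summaries), and
#' `manifest.json` recording the seed, a configuration hash and the
#' package version. Every file declares its schema version.
#'
#' @param cohort A `mel_cohort` (with events for `events.csv`).
#' @param destination Directory (created if missing).
#' @param params The parameter set used (hashed into the manifest).
#' @return Invisible character vector of written paths.
#' @export
write_outputs <- function(cohort, destination, params = NULL) {
  dir.create(destination, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(destination))
    stop("destination is not writable: ", destination)
  paths <- character(0)
  if (!is.null(cohort$histories[[1L]]$events)) {
    ev <- events_table(cohort)
    p <- file.path(destination, "events.csv")
    .write_schema_csv(ev, p, "melscreen-events-1")
    paths <- c(paths, p)
  }
  tt <- tumours_table(cohort)
  p <- file.path(destination, "tumours.csv")
  .write_schema_csv(tt, p, "melscreen-tumours-1")
  paths <- c(paths, p)
  sm <- compute_summaries(cohort)
  p <- file.path(destination, "summary.csv")
  .write_schema_csv(sm, p, "melscreen-summary-1")
  paths <- c(paths, p)
  cfg_hash <- NA_character_
  if (!is.null(params)) {
    tmp <- tempfile(fileext = ".yaml")
    write_parameters(params, tmp)
    cfg_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  }
  manifest <- list(schema = "melscreen-manifest-1",
                   seed = cohort$seed, n = cohort$n,
                   config_hash = cfg_hash,
                   policy = if (is.null(cohort$policy)) "none"
                            else unclass(cohort$policy),
                   package_version =
                     as.character(utils::packageVersion("melscreen")))
  p <- file.path(destination, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}

#' Read a summary CSV written by [write_outputs()]
#'
#' @param path Path to `summary.csv`.
#' @return A data frame.
#' @export
read_summary <- function(path)
  .read_schema_csv(path, "melscreen-summary-1")

#' Configuration hash of a parameter set
#'
#' @param params A `mel_parameters` object.
#' @return MD5 hash string of the serialised configuration.
#' @export
config_hash <- function(params) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_parameters(params, tmp)
  unname(tools::md5sum(tmp))
}
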