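#' Bundle the four relational registry tables
#'
#' Container for the longitudinal registry extract that every analysis stage
#' consumes: patients (demographics), visits (EDSS assessments), relapses
#' (onset dates) and treatments (drug episodes). Dates are held internally as
#' integer day offsets from `meta$origin` (calendar formatting happens only at
#' [write_registry()] / [read_registry()] time). Referential integrity —
#' every visit, relapse and episode pointing at an existing patient — is
#' enforced at construction.
#'
#' @param patients `data.frame` with columns `patient_id`, `sex`,
#'   `birth_year`, `onset_date`, `country`, `source`.
#' @param visits `data.frame` with columns `patient_id`, `date`, `edss`.
#' @param relapses `data.frame` with columns `patient_id`, `date`.
#' @param treatments `data.frame` with columns `patient_id`, `drug`,
#'   `start_date`, `end_date` (`NA` end = episode ongoing at data cut).
#' @param meta List of provenance metadata; `origin` (ISO date of day 0) and
#'   `availability_day` (first day the control drug could be prescribed)
#'   default to "2011-01-01" and 0.
#' @return A `registry_tables` object.
#' @export
registry_tables <- function(patients, visits, relapses, treatments,
                            meta = list()) {
  req <- list(
    patients = c("patient_id", "sex", "birth_year", "onset_date", "country",
                 "source"),
    visits = c("patient_id", "date", "edss"),
    relapses = c("patient_id", "date"),
    treatments = c("patient_id", "drug", "start_date", "end_date")
  )
  tabs <- list(patients = patients, visits = visits, relapses = relapses,
               treatments = treatments)
  for (nm in names(req)) {
    miss <- setdiff(req[[nm]], names(tabs[[nm]]))
    if (length(miss))
      stop(sprintf("registry table '%s' lacks column(s): %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
    tabs[[nm]] <- as.data.table(tabs[[nm]])
  }
  ids <- tabs$patients$patient_id
  if (anyDuplicated(ids))
    stop("duplicate patient_id in patients table", call. = FALSE)
  for (nm in c("visits", "relapses", "treatments")) {
    orphan <- setdiff(tabs[[nm]]$patient_id, ids)
    if (length(orphan))
      stop(sprintf("table '%s' references unknown patient_id(s): %s", nm,
                   paste(head(orphan, 5), collapse = ", ")), call. = FALSE)
  }
  bad <- with(tabs$treatments, !is.na(end_date) & end_date < start_date)
  if (any(bad))
    stop("treatments table has episodes with end before start", call. = FALSE)
  meta$origin <- meta$origin %||% "2011-01-01"
  meta$availability_day <- meta$availability_day %||% 0
  structure(c(tabs, list(meta = meta)), class = "registry_tables")
}

#' @export
print.registry_tables <- function(x, ...) {
  cat("<registry_tables>\n")
  cat(sprintf("  %d patients | %d visits | %d relapses | %d treatment episodes\n",
              nrow(x$patients), nrow(x$visits), nrow(x$relapses),
              nrow(x$treatments)))
  cat("  origin:", x$meta$origin,
      "| availability day:", x$meta$availability_day, "\n")
  invisible(x)
}

#' Write a registry (and optional ground truth) to CSV files
#'
#' Serializes the four tables with ISO-8601 calendar dates (converted from
#' the internal day offsets using `meta$origin`). When `truth` is supplied a
#' `ground_truth.csv` is written alongside, and the generator configuration
#' echo goes to `config.json`.
#'
#' @param registry A `registry_tables` object.
#' @param dir Output directory (created if absent).
#' @param truth Optional ground-truth `data.table` from [generate_registry()].
#' @param config Optional [simulation_config()] echo.
#' @return Invisibly, the vector of files written.
#' @export
write_registry <- function(registry, dir, truth = NULL, config = NULL) {
  stopifnot(inherits(registry, "registry_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  origin <- as.Date(registry$meta$origin)
  as_iso <- function(d) ifelse(is.na(d), "", as.character(origin + round(d)))
  files <- character()
  conv <- list(
    patients = function(t) {
      t <- copy(t); t[, onset_date := as_iso(onset_date)]; t
    },
    visits = function(t) { t <- copy(t); t[, date := as_iso(date)]; t },
    relapses = function(t) { t <- copy(t); t[, date := as_iso(date)]; t },
    treatments = function(t) {
      t <- copy(t)
      t[, `:=`(start_date = as_iso(start_date), end_date = as_iso(end_date))]
      t
    }
  )
  for (nm in names(conv)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    fwrite(conv[[nm]](registry[[nm]]), path)
    files <- c(files, path)
  }
  if (!is.null(truth)) {
    path <- file.path(dir, "ground_truth.csv")
    fwrite(as.data.table(truth), path)
    files <- c(files, path)
  }
  if (!is.null(config)) {
    path <- file.path(dir, "config.json")
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    files <- c(files, path)
  }
  invisible(files)
}

#' Read a registry written by [write_registry()]
#'
#' @param dir Directory holding `patients.csv`, `visits.csv`, `relapses.csv`
#'   and `treatments.csv` with ISO-8601 dates.
#' @param origin ISO date mapped to internal day 0.
#' @param availability_day Day offset at which the control drug became
#'   available.
#' @return A `registry_tables` object with integer day offsets.
#' @export
read_registry <- function(dir, origin = "2011-01-01", availability_day = 0) {
  o <- as.Date(origin)
  to_day <- function(x) {
    x[x == ""] <- NA
    as.numeric(as.Date(x) - o)
  }
  pa <- fread(file.path(dir, "patients.csv"), colClasses = list(character = "onset_date"))
  vi <- fread(file.path(dir, "visits.csv"), colClasses = list(character = "date"))
  re <- fread(file.path(dir, "relapses.csv"), colClasses = list(character = "date"))
  tr <- fread(file.path(dir, "treatments.csv"),
              colClasses = list(character = c("start_date", "end_date")))
  pa[, onset_date := to_day(onset_date)]
  vi[, date := to_day(date)]
  re[, date := to_day(date)]
  tr[, `:=`(start_date = to_day(start_date), end_date = to_day(end_date))]
  registry_tables(pa, vi, re, tr,
                  meta = list(origin = origin,
                              availability_day = availability_day))
}

#' Last recorded day per patient
#'
#' The latest date observed for each patient across visits, relapses and
#' treatment episodes — the administrative end of follow-up used by the
#' censoring contrasts.
#'
#' @param registry A `registry_tables` object.
#' @return `data.table` with `patient_id` and `last_record`.
#' @export
last_record_table <- function(registry) {
  .last_record_table(registry)
}

# per-patient last recorded day across all tables
.last_record_table <- function(registry) {
  pieces <- rbind(
    registry$visits[, .(patient_id, day = date)],
    registry$relapses[, .(patient_id, day = date)],
    registry$treatments[, .(patient_id, day = start_date)],
    registry$treatments[!is.na(end_date), .(patient_id, day = end_date)]
  )
  pieces[, .(last_record = max(day)), by = patient_id]
}
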