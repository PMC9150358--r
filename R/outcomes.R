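# Outcome derivation from longitudinal visit/relapse data: relapse counts,
# time to first relapse, confirmed EDSS worsening/improvement with six-month
# sustained confirmation, annualized visit density, reverse Kaplan-Meier
# follow-up summaries.

#' Confirmation parameters for EDSS change detection
#'
#' Defaults encode the study definitions: a change must be sustained at all
#' consecutive visits over at least six months (180 days), and a worsening
#' confirmation cannot fall within 30 days after a relapse onset. Thresholds
#' depend on the reference EDSS: worsening needs +1.5 steps from EDSS 0,
#' +1.0 up to 5.5, +0.5 above 5.5; improvement needs -1.5 from EDSS 1.5,
#' -1.0 for 2.0-6.0, -0.5 above 6.0 (undefined below 1.5).
#'
#' @param confirmation_days Minimum sustained duration, days.
#' @param relapse_exclusion_days Days after a relapse onset during which a
#'   visit cannot confirm worsening.
#' @return List of class `confirmation_params`.
#' @export
confirmation_params <- function(confirmation_days = 180,
                                relapse_exclusion_days = 30) {
  stopifnot(confirmation_days > 0, relapse_exclusion_days >= 0)
  structure(list(confirmation_days = confirmation_days,
                 relapse_exclusion_days = relapse_exclusion_days),
            class = "confirmation_params")
}

#' Count relapses within an analysis window
#'
#' Counts relapse onsets in the half-open window `(start, end]` (an onset on
#' the index day belongs to baseline history) and returns the exposure time.
#'
#' @param relapses Numeric vector of relapse onset days.
#' @param window Numeric `c(start, end)` in days.
#' @return List with `count` and `exposure_days`.
#' @export
count_relapses <- function(relapses, window) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  list(count = sum(relapses > window[1] & relapses <= window[2]),
       exposure_days = window[2] - window[1])
}

#' Time to first relapse within an analysis window
#'
#' @param relapses Numeric vector of relapse onset days.
#' @param window Numeric `c(start, end)` in days.
#' @return List with `event` (0/1), `event_day` (days since window start, NA
#'   if censored) and `followup_days`.
#' @export
time_to_first_relapse <- function(relapses, window) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  inw <- relapses[relapses > window[1] & relapses <= window[2]]
  if (length(inw))
    list(event = 1L, event_day = min(inw) - window[1],
         followup_days = window[2] - window[1])
  else
    list(event = 0L, event_day = NA_real_,
         followup_days = window[2] - window[1])
}

#' Detect a confirmed EDSS worsening or improvement event
#'
#' Scans in-window visits in date order. A candidate onset is the first visit
#' whose EDSS change from baseline meets the direction's threshold for the
#' baseline score. The candidate is confirmed if some visit at least
#' `confirmation_days` later exists such that every visit from onset through
#' that confirming visit (inclusive) meets the threshold; for worsening the
#' confirming visit must not fall within `relapse_exclusion_days` after any
#' relapse onset. On confirmation the event is timed at the onset visit. A
#' failed candidate (an intermediate visit below threshold) is discarded and
#' scanning resumes after the failing visit. Improvement is structurally
#' censored when baseline EDSS is below 1.5.
#'
#' @param visits `data.frame` with columns `day`, `edss` (half-point grid).
#' @param relapses Numeric vector of relapse onset days (used only for the
#'   worsening confirmation exclusion).
#' @param baseline_edss Fixed baseline EDSS on the half-point grid.
#' @param direction `"worsening"` or `"improvement"`.
#' @param params [confirmation_params()].
#' @param window Numeric `c(start, end)`; only visits in `(start, end]` are
#'   scanned.
#' @return List with `event` (0/1), `event_day` (onset day minus window
#'   start; NA if censored), `followup_days`, and `structural` (TRUE when
#'   improvement is undefined for the baseline score).
#' @export
detect_confirmed_change <- function(visits, relapses = numeric(),
                                    baseline_edss,
                                    direction = c("worsening", "improvement"),
                                    params = confirmation_params(),
                                    window) {
  direction <- match.arg(direction)
  stopifnot(length(window) == 2, window[2] >= window[1])
  if (!.on_edss_grid(baseline_edss))
    stop("baseline EDSS must be on the half-point grid 0-10", call. = FALSE)
  if (any(!.on_edss_grid(visits$edss)))
    stop("visit EDSS values must be on the half-point grid 0-10",
         call. = FALSE)
  .detect_scan(visits$day, visits$edss, relapses, baseline_edss, direction,
               params, window[1], window[2])
}

# scanning core shared with the vectorized builders (inputs pre-validated)
.detect_scan <- function(v_day, v_edss, relapses, baseline_edss, direction,
                         params, w0, w1) {
  fu <- w1 - w0
  censored <- function(structural = FALSE)
    list(event = 0L, event_day = NA_real_, followup_days = fu,
         structural = structural)
  if (direction == "improvement" && baseline_edss < 1.5)
    return(censored(structural = TRUE))
  keep <- v_day > w0 & v_day <= w1
  v_day <- v_day[keep]; v_edss <- v_edss[keep]
  if (is.unsorted(v_day)) {
    o <- order(v_day)
    v_day <- v_day[o]; v_edss <- v_edss[o]
  }
  m <- length(v_day)
  if (m == 0L) return(censored())
  if (direction == "worsening") {
    step <- worsening_step(baseline_edss)
    meets <- v_edss - baseline_edss >= step - 1e-9
  } else {
    step <- improvement_step(baseline_edss)
    meets <- baseline_edss - v_edss >= step - 1e-9
  }
  rel <- relapses[relapses <= w1]
  check_rel <- direction == "worsening" && length(rel) > 0L
  i <- 1L
  while (i <= m) {
    if (!meets[i]) { i <- i + 1L; next }
    onset <- v_day[i]
    j <- i + 1L
    fail_at <- NA_integer_
    while (j <= m) {
      if (!meets[j]) { fail_at <- j; break }
      if (v_day[j] >= onset + params$confirmation_days &&
          !(check_rel && any(v_day[j] > rel &
                             v_day[j] <= rel + params$relapse_exclusion_days))) {
        return(list(event = 1L, event_day = onset - w0,
                    followup_days = fu, structural = FALSE))
      }
      j <- j + 1L
    }
    if (is.na(fail_at)) return(censored())  # ran out of confirming visits
    i <- fail_at + 1L
  }
  censored()
}

#' Annualized EDSS visit density
#'
#' @param visits Numeric vector of visit days (or `data.frame` with a `day`
#'   column).
#' @param window Numeric `c(start, end)`, strictly positive length.
#' @return Visits per follow-up year.
#' @export
visit_density <- function(visits, window) {
  stopifnot(length(window) == 2)
  if (window[2] <= window[1])
    stop("visit_density: zero-length window", call. = FALSE)
  d <- if (is.data.frame(visits)) visits$day else visits
  sum(d > window[1] & d <= window[2]) / ((window[2] - window[1]) / 365.25)
}

#' Median follow-up by the reverse Kaplan-Meier estimator
#'
#' Estimates median follow-up accounting for its completeness by inverting
#' the censoring indicator: being censored for the outcome is the "event",
#' outcome events are censored observations. Confidence limits use the
#' log-log transform.
#'
#' @param followups Numeric follow-up times.
#' @param events 0/1 outcome-event indicators.
#' @return List with `median` and `ci` (95% limits; `NA` = not reached).
#' @export
reverse_km_median <- function(followups, events) {
  stopifnot(length(followups) > 0, length(followups) == length(events))
  fit <- survival::survfit(Surv(followups, 1 - events) ~ 1,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  list(median = unname(tab["median"]),
       ci = c(unname(tab["0.95LCL"]), unname(tab["0.95UCL"])))
}

# --- vectorized outcome-record builder ---------------------------------------

#' Derive per-patient outcome records for one outcome under given windows
#'
#' Applies the outcome definition to every patient's in-window data and
#' returns the analysis-ready record table: counts with exposure for the
#' relapse-count outcome, or time/event pairs (plus annualized visit density)
#' for the time-to-event outcomes. Patients with zero-length windows are
#' dropped with an attribute noting them.
#'
#' @param registry A `registry_tables` object.
#' @param baseline Baseline table from [apply_eligibility()].
#' @param windows Analysis windows from the contrasts module
#'   (`patient_id`, `start`, `end`, `reason`).
#' @param outcome One of `"relapse_count"`, `"first_relapse"`,
#'   `"worsening"`, `"improvement"`.
#' @param params [confirmation_params()].
#' @return `data.table` of outcome records; time-to-event rows carry
#'   `time` = event day when an event occurred, else the follow-up length.
#' @export
derive_outcome_records <- function(registry, baseline, windows,
                                   outcome = c("relapse_count",
                                               "first_relapse", "worsening",
                                               "improvement"),
                                   params = confirmation_params()) {
  outcome <- match.arg(outcome)
  w <- as.data.table(windows)
  bl <- as.data.table(baseline)
  w <- merge(w, bl[, .(patient_id, arm, baseline_edss)], by = "patient_id")
  zero <- w[end <= start, patient_id]
  w <- w[end > start]
  rel <- registry$relapses[patient_id %in% w$patient_id]
  if (outcome == "relapse_count") {
    cnt <- rel[w, on = .(patient_id, date > start, date <= end), nomatch = NULL,
               .N, by = .EACHI][, .(patient_id, count = N)]
    out <- merge(w[, .(patient_id, arm, exposure_days = end - start)],
                 cnt, by = "patient_id", all.x = TRUE)
    out[is.na(count), count := 0L]
  } else if (outcome == "first_relapse") {
    frst <- rel[w, on = .(patient_id, date > start, date <= end),
                nomatch = NULL, .(first = min(x.date)), by = .EACHI][
                  , .(patient_id, first)]
    out <- merge(w[, .(patient_id, arm, start, end)], frst,
                 by = "patient_id", all.x = TRUE)
    out[, `:=`(event = as.integer(!is.na(first)),
               event_day = first - start,
               followup_days = end - start)]
    out[, time := fifelse(event == 1L, event_day, followup_days)]
    out <- .add_visit_density(out, registry)
    out <- out[, .(patient_id, arm, time, event, event_day, followup_days,
                   visit_density)]
  } else {
    direction <- outcome
    vis <- registry$visits[patient_id %in% w$patient_id][order(patient_id, date)]
    vdays <- split(vis$date, vis$patient_id)
    vedss <- split(vis$edss, vis$patient_id)
    rdays <- split(rel$date, rel$patient_id)
    np <- nrow(w)
    ev <- integer(np); evd <- numeric(np); fud <- numeric(np)
    str <- logical(np)
    for (k in seq_len(np)) {
      key <- as.character(w$patient_id[k])
      res <- .detect_scan(vdays[[key]] %||% numeric(),
                          vedss[[key]] %||% numeric(),
                          rdays[[key]] %||% numeric(),
                          w$baseline_edss[k], direction, params,
                          w$start[k], w$end[k])
      ev[k] <- res$event; evd[k] <- res$event_day
      fud[k] <- res$followup_days; str[k] <- res$structural
    }
    out <- data.table(patient_id = w$patient_id, arm = w$arm, event = ev,
                      event_day = evd, followup_days = fud, structural = str)
    out[, time := fifelse(event == 1L, event_day, followup_days)]
    out <- merge(out, w[, .(patient_id, start, end)], by = "patient_id")
    out <- .add_visit_density(out, registry)
    out <- out[, .(patient_id, arm, time, event, event_day, followup_days,
                   visit_density, structural)]
  }
  setattr(out, "outcome", outcome)
  setattr(out, "zero_length_windows", zero)
  out[]
}

.add_visit_density <- function(out, registry) {
  vis <- registry$visits[patient_id %in% out$patient_id]
  vd <- vis[out, on = .(patient_id, date > start, date <= end),
            nomatch = NULL, .N, by = .EACHI][, .(patient_id, n_vis = N)]
  out <- merge(out, vd, by = "patient_id", all.x = TRUE)
  out[is.na(n_vis), n_vis := 0L]
  out[, visit_density := n_vis / ((end - start) / 365.25)]
  out[, n_vis := NULL]
  out
}
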