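# Cohort construction: index-episode selection, eligibility screening and the
# baseline covariate table the propensity model consumes.
#
# Operational constants: "six months" = 183 days, "12 months" = 365 days,
# "three months" = 90 days, for day-resolution determinism.

.PRE_WINDOW <- 183
.POST_GAP <- 183
.MIN_EXPOSURE <- 90
.LOOKBACK <- 365

# merge overlapping same-drug episodes; returns list(treatments, n_merged)
.merge_episodes <- function(tr) {
  tr <- as.data.table(tr)[order(patient_id, drug, start_date)]
  tr[, e := ifelse(is.na(end_date), Inf, end_date)]
  tr[, grp := {
    ce <- cummax(shift(e, fill = -Inf))
    cumsum(start_date > ce)
  }, by = .(patient_id, drug)]
  n_in <- nrow(tr)
  out <- tr[, .(start_date = min(start_date),
                end_date = if (any(is.na(end_date))) NA_real_ else max(end_date)),
            by = .(patient_id, drug, grp)]
  out[, grp := NULL]
  list(treatments = out[order(patient_id, start_date)],
       n_merged = n_in - nrow(out))
}

#' Select the index treatment episode for each patient
#'
#' The index episode is the earliest study-drug episode starting on or after
#' the availability date of the control drug (unless `allow_pre_era`, the
#' positivity sensitivity mode) and continued for at least three months
#' (90 days); open-ended episodes qualify if observed for at least 90 days.
#' Patients with any prior exposure to a therapy with extended duration of
#' effect (mitoxantrone, alemtuzumab, cladribine, daclizumab, rituximab,
#' ocrelizumab) or off-label cyclophosphamide before the candidate start are
#' excluded. Overlapping same-drug episodes are merged with a warning.
#'
#' @param treatments Treatment episode table (`patient_id`, `drug`,
#'   `start_date`, `end_date`; `NA` end = ongoing).
#' @param availability_day Day offset on/after which both drugs are
#'   prescribable.
#' @param allow_pre_era Include episodes starting before availability
#'   (violates positivity; sensitivity analyses only).
#' @param last_record Optional `data.frame(patient_id, last_record)` used to
#'   judge the observed duration of open-ended episodes; defaults to the
#'   latest date in `treatments` itself.
#' @param study_drugs Length-2 character vector, treated drug first.
#' @param excluded_drugs Drugs whose prior use disqualifies a patient.
#' @return `data.table` with one row per indexed patient: `patient_id`,
#'   `drug`, `arm` (factor control/treated), `index_day`, `episode_end`,
#'   `last_record`; attribute `excluded` lists patients dropped for prior
#'   excluded-drug exposure.
#' @export
select_index_episode <- function(treatments, availability_day = 0,
                                 allow_pre_era = FALSE, last_record = NULL,
                                 study_drugs = c("natalizumab", "fingolimod"),
                                 excluded_drugs = .excluded_drugs) {
  m <- .merge_episodes(treatments)
  if (m$n_merged > 0)
    warning(sprintf("merged %d overlapping same-drug episode(s)", m$n_merged),
            call. = FALSE)
  tr <- m$treatments
  if (is.null(last_record)) {
    last_record <- tr[, .(last_record = max(c(start_date, end_date),
                                            na.rm = TRUE)), by = patient_id]
  } else {
    last_record <- as.data.table(last_record)
  }
  cand <- tr[drug %in% study_drugs]
  if (!allow_pre_era) cand <- cand[start_date >= availability_day]
  cand <- merge(cand, last_record, by = "patient_id")
  cand[, obs_end := pmin(ifelse(is.na(end_date), Inf, end_date), last_record)]
  cand <- cand[obs_end - start_date >= .MIN_EXPOSURE]
  idx <- cand[order(patient_id, start_date), .SD[1L], by = patient_id]
  # prior exposure to an excluded therapy disqualifies
  excl_tr <- tr[drug %in% excluded_drugs]
  if (nrow(excl_tr)) {
    excl_ep <- excl_tr[, .(first_excl = min(start_date)), by = patient_id]
    idx <- merge(idx, excl_ep, by = "patient_id", all.x = TRUE)
  } else {
    idx[, first_excl := NA_real_]
  }
  dropped <- idx[!is.na(first_excl) & first_excl < start_date, patient_id]
  idx <- idx[!patient_id %in% dropped]
  out <- idx[, .(patient_id, drug,
                 arm = factor(ifelse(drug == study_drugs[1], "treated",
                                     "control"),
                              levels = c("control", "treated")),
                 index_day = start_date, episode_end = end_date, last_record)]
  setattr(out, "excluded",
          data.table(patient_id = dropped, reason = "prior excluded drug"))
  out[]
}

#' Apply the eligibility criteria and derive the baseline table
#'
#' Retains indexed patients with (a) an EDSS visit within the six-month
#' window before (and including) the index date — the most recent one is the
#' baseline visit; (b) at least two post-baseline EDSS visits at least six
#' months apart; and (c) at least one EDSS visit during the index episode
#' (the index-day visit counts). Each patient contributes once.
#'
#' @param registry A `registry_tables` object.
#' @param index Index assignment table from [select_index_episode()].
#' @param params [confirmation_params()] used by the prior-activity worsening
#'   detector.
#' @return List with `baseline` (one [derive_baseline()]-style record per
#'   eligible patient) and `report` (per-patient criterion flags and
#'   per-criterion exclusion counts).
#' @export
apply_eligibility <- function(registry, index, params = confirmation_params()) {
  stopifnot(inherits(registry, "registry_tables"))
  idx <- as.data.table(index)
  vis <- registry$visits[patient_id %in% idx$patient_id]
  vis <- merge(vis, idx[, .(patient_id, index_day, episode_end, last_record)],
               by = "patient_id")
  # (a) baseline EDSS within [index - 183, index]
  pre <- vis[date >= index_day - .PRE_WINDOW & date <= index_day]
  base <- pre[order(patient_id, date), .SD[.N], by = patient_id,
              .SDcols = c("date", "edss")]
  setnames(base, c("date", "edss"), c("baseline_edss_day", "baseline_edss"))
  # (b) two post-baseline visits >= 183 days apart
  post <- vis[date > index_day,
              .(n_post = .N, span = max(date) - min(date)), by = patient_id]
  # (c) at least one on-treatment visit (index day included)
  ontr <- vis[date >= index_day &
                date <= pmin(ifelse(is.na(episode_end), Inf, episode_end),
                             last_record),
              .(n_on = .N), by = patient_id]
  rep_dt <- idx[, .(patient_id)]
  rep_dt <- merge(rep_dt, base[, .(patient_id, baseline_edss_day)],
                  by = "patient_id", all.x = TRUE)
  rep_dt <- merge(rep_dt, post, by = "patient_id", all.x = TRUE)
  rep_dt <- merge(rep_dt, ontr, by = "patient_id", all.x = TRUE)
  rep_dt[, `:=`(
    has_baseline_edss = !is.na(baseline_edss_day),
    has_two_post_visits = !is.na(n_post) & n_post >= 2 & span >= .POST_GAP,
    has_on_treatment_visit = !is.na(n_on) & n_on >= 1
  )]
  rep_dt[, eligible := has_baseline_edss & has_two_post_visits &
           has_on_treatment_visit]
  counts <- data.table(
    criterion = c("baseline EDSS within 6 months",
                  "two post-baseline visits >= 6 months apart",
                  "on-treatment EDSS visit"),
    n_failed = c(sum(!rep_dt$has_baseline_edss),
                 sum(!rep_dt$has_two_post_visits),
                 sum(!rep_dt$has_on_treatment_visit))
  )
  keep <- rep_dt[eligible == TRUE, patient_id]
  baseline <- .derive_baseline_all(registry, idx[patient_id %in% keep],
                                   base[patient_id %in% keep], params)
  list(baseline = baseline,
       report = list(
         per_patient = rep_dt[, .(patient_id, has_baseline_edss,
                                  has_two_post_visits, has_on_treatment_visit,
                                  eligible)],
         counts = counts,
         n_indexed = nrow(idx), n_eligible = length(keep)))
}

# vectorized baseline derivation for all eligible patients
.derive_baseline_all <- function(registry, idx, base, params) {
  pa <- registry$patients[patient_id %in% idx$patient_id]
  if (any(is.na(pa$onset_date)))
    stop("missing MS onset date for patient(s): ",
         paste(head(pa[is.na(onset_date), patient_id], 5), collapse = ", "),
         call. = FALSE)
  origin_year <- as.integer(format(as.Date(registry$meta$origin), "%Y"))
  bl <- merge(idx[, .(patient_id, arm, drug, index_day, episode_end,
                      last_record)],
              pa[, .(patient_id, sex, birth_year, onset_date, country, source)],
              by = "patient_id")
  bl <- merge(bl, base, by = "patient_id")
  bl[, age := (origin_year + index_day / 365.25) - birth_year]
  bl[, ms_duration := (index_day - onset_date) / 365.25]
  if (any(bl$ms_duration < 0 | bl$age < 0))
    stop("negative age or MS duration at index", call. = FALSE)
  rel <- registry$relapses[patient_id %in% bl$patient_id]
  rel <- merge(rel, bl[, .(patient_id, index_day)], by = "patient_id")
  nrel <- rel[date >= index_day - .LOOKBACK & date < index_day, .N,
              by = patient_id]
  bl <- merge(bl, nrel, by = "patient_id", all.x = TRUE)
  setnames(bl, "N", "n_relapses_prior_12m")
  bl[is.na(n_relapses_prior_12m), n_relapses_prior_12m := 0L]
  tx <- registry$treatments[patient_id %in% bl$patient_id]
  tx <- merge(tx, bl[, .(patient_id, index_day)], by = "patient_id")
  ntx <- tx[start_date < index_day, .N, by = patient_id]
  bl <- merge(bl, ntx, by = "patient_id", all.x = TRUE)
  setnames(bl, "N", "n_prior_treatments")
  bl[is.na(n_prior_treatments), n_prior_treatments := 0L]
  wflag <- .prior_worsening_flags(registry, bl, params)
  bl <- merge(bl, wflag, by = "patient_id")
  bl[, prior_activity := factor(
    fifelse(n_relapses_prior_12m >= 1,
            fifelse(prior_worsening, "relapse and worsening", "relapse"),
            fifelse(prior_worsening, "worsening", "none")),
    levels = c("none", "worsening", "relapse", "relapse and worsening"))]
  out <- bl[, .(patient_id, arm, drug, index_day, episode_end, last_record,
                sex, age, ms_duration, baseline_edss, baseline_edss_day,
                n_prior_treatments, n_relapses_prior_12m, prior_activity,
                country, source)]
  setattr(out, "class", c("baseline_table", class(out)))
  out[]
}

# confirmed worsening in the 12-month pre-index window, anchored on the
# earliest EDSS in that window as reference (the paper gives no operational
# rule for pre-baseline worsening; this reuses the outcome detector)
.prior_worsening_flags <- function(registry, bl, params) {
  vis <- registry$visits[patient_id %in% bl$patient_id]
  vis <- merge(vis, bl[, .(patient_id, index_day)], by = "patient_id")
  win <- vis[date >= index_day - .LOOKBACK & date <= index_day]
  if (nrow(win) == 0L)
    return(data.table(patient_id = bl$patient_id, prior_worsening = FALSE))
  setorder(win, patient_id, date)
  # cheap screen: no candidate if the range never reaches the smallest step
  rng <- win[, .(ref = edss[1L], mx = max(edss), n = .N), by = patient_id]
  need <- rng[n >= 2 & mx - ref >= worsening_step(ref) - 1e-9, patient_id]
  wn <- win[patient_id %in% need]
  vdays <- split(wn$date, wn$patient_id)
  vedss <- split(wn$edss, wn$patient_id)
  idays <- split(wn$index_day, wn$patient_id)
  rel <- registry$relapses[patient_id %in% need]
  rdays <- split(rel$date, rel$patient_id)
  hit <- logical(length(need))
  for (k in seq_along(need)) {
    key <- as.character(need[k])
    d <- vdays[[key]]; e <- vedss[[key]]
    res <- .detect_scan(d[-1L], e[-1L], rdays[[key]] %||% numeric(),
                        e[1L], "worsening", params,
                        d[1L], idays[[key]][1L])
    hit[k] <- res$event == 1L
  }
  data.table(patient_id = bl$patient_id,
             prior_worsening = bl$patient_id %in% need[hit])
}

#' Derive the baseline record for a single patient
#'
#' Convenience single-patient wrapper around the vectorized baseline
#' derivation: baseline EDSS is the most recent score in the six months up to
#' and including the index date, relapses are counted over `[index - 365,
#' index)`, prior treatments as distinct pre-index episodes, MS duration from
#' first symptoms to index, and prior clinical activity from both the relapse
#' count and a confirmed-worsening scan over the 12-month lookback.
#'
#' @param patient One-row `data.frame` with `patient_id`, `sex`,
#'   `birth_year`, `onset_date`, `country`, `source`.
#' @param visits,relapses,treatments The patient's rows of the registry
#'   tables.
#' @param index_date Index day offset.
#' @param params [confirmation_params()].
#' @param origin ISO date mapped to day 0 (for age at index).
#' @return One-row baseline record `data.table`.
#' @export
derive_baseline <- function(patient, visits, relapses, treatments, index_date,
                            params = confirmation_params(),
                            origin = "2011-01-01") {
  if (is.na(patient$onset_date))
    stop("missing MS onset date", call. = FALSE)
  reg <- registry_tables(patient, visits,
                         if (nrow(relapses)) relapses
                         else data.frame(patient_id = integer(), date = numeric()),
                         treatments, meta = list(origin = origin))
  tr <- as.data.table(treatments)
  ep <- tr[start_date == index_date & drug %in% .study_drugs]
  arm <- if (nrow(ep)) factor(ifelse(ep$drug[1] == "natalizumab", "treated",
                                     "control"),
                              levels = c("control", "treated"))
         else factor(NA, levels = c("control", "treated"))
  lr <- .last_record_table(reg)
  idx <- data.table(patient_id = patient$patient_id,
                    drug = if (nrow(ep)) ep$drug[1] else NA_character_,
                    arm = arm, index_day = index_date,
                    episode_end = if (nrow(ep)) ep$end_date[1] else NA_real_,
                    last_record = lr$last_record[1])
  pre <- reg$visits[date >= index_date - .PRE_WINDOW & date <= index_date]
  if (!nrow(pre))
    stop("no baseline EDSS visit within the 6-month pre-index window",
         call. = FALSE)
  base <- pre[order(date), .SD[.N]][, .(patient_id,
                                        baseline_edss_day = date,
                                        baseline_edss = edss)]
  .derive_baseline_all(reg, idx, base, params)
}
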