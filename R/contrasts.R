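# Causal contrasts: per-patient analysis windows under intention-to-treat,
# per-protocol and pairwise censoring.
#
# Outcome events falling exactly on the window end are included (closed right
# endpoint), so boundary behavior is deterministic.

#' Intention-to-treat analysis windows
#'
#' Follow-up runs from the index date to the last recorded data entry,
#' regardless of later treatment changes. A zero-length window (last record
#' on the index day) is kept but flagged via the `reason`.
#'
#' @param index Index table (`patient_id`, `index_day`, `last_record`), as
#'   returned by [select_index_episode()] or carried on the baseline table.
#' @return `data.table` with `patient_id`, `start`, `end`, `reason`.
#' @export
censor_itt <- function(index) {
  idx <- as.data.table(index)
  stopifnot(all(c("patient_id", "index_day", "last_record") %in% names(idx)))
  if (any(idx$last_record < idx$index_day))
    stop("last record precedes the index date", call. = FALSE)
  idx[, .(patient_id, start = index_day, end = last_record,
          reason = ifelse(last_record == index_day, "degenerate",
                          "last record"))]
}

#' Per-protocol analysis windows
#'
#' Follow-up runs from the index date until treatment discontinuation (the
#' index-episode end) or the last data entry, whichever occurs earlier;
#' episodes ongoing at the data cut are censored at the last record.
#'
#' @param index Index table (`patient_id`, `index_day`, `episode_end`,
#'   `last_record`).
#' @return `data.table` with `patient_id`, `start`, `end`, `reason`.
#' @export
censor_per_protocol <- function(index) {
  idx <- as.data.table(index)
  stopifnot(all(c("patient_id", "index_day", "episode_end", "last_record")
                %in% names(idx)))
  if (any(idx$last_record < idx$index_day))
    stop("last record precedes the index date", call. = FALSE)
  idx[, {
    ep <- ifelse(is.na(episode_end), Inf, episode_end)
    end <- pmin(ep, last_record)
    .(patient_id = patient_id, start = index_day, end = end,
      reason = ifelse(end == last_record & ep > last_record, "last record",
                      "discontinuation"))
  }]
}

#' Pairwise censoring of matched follow-up
#'
#' Within each matched pair, both members are truncated to the pair's
#' shorter follow-up, preserving the balance of analysed time between the
#' arms. Idempotent; never lengthens a window.
#'
#' @param windows Window table from [censor_itt()] or
#'   [censor_per_protocol()].
#' @param matched A `matched_cohort`.
#' @return Window table restricted to matched patients, with truncated
#'   members labelled `reason = "pairwise"`.
#' @export
censor_pairwise <- function(windows, matched) {
  stopifnot(inherits(matched, "matched_cohort"))
  w <- as.data.table(windows)
  pr <- matched$pairs
  need <- unique(c(pr$treated_id, pr$control_id))
  missing_ids <- setdiff(need, w$patient_id)
  if (length(missing_ids))
    stop("matched patient(s) without an analysis window: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  long <- rbind(pr[, .(pair_id, patient_id = treated_id)],
                pr[, .(pair_id, patient_id = control_id)])
  w2 <- merge(w, long, by = "patient_id")
  w2[, len := end - start]
  w2[, min_len := min(len), by = pair_id]
  out <- w2[, .(patient_id, start, end = start + min_len,
                reason = ifelse(len > min_len, "pairwise", reason),
                pair_id)]
  out[]
}
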