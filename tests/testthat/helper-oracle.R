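# Independent step-by-step greedy matching oracle: processes treated patients
# in the given order, assigning the nearest unused control within the caliper
# by explicit scan. Deliberately naive; shares no code with match_greedy.
oracle_greedy <- function(ps_t, id_t, ps_c, id_c, caliper_abs, order) {
  used <- rep(FALSE, length(ps_c))
  out <- NULL
  for (i in order) {
    best <- NA_integer_
    best_d <- Inf
    for (j in seq_along(ps_c)) {
      if (used[j]) next
      d <- abs(ps_c[j] - ps_t[i])
      if (d < best_d - 1e-15) { best_d <- d; best <- j }
    }
    if (!is.na(best) && best_d <= caliper_abs + 1e-12) {
      used[best] <- TRUE
      out <- rbind(out, data.frame(treated_id = id_t[i], control_id = id_c[best],
                                   distance = best_d))
    }
  }
  out
}

# independent predicate checker for a claimed confirmed-change event
verify_event_predicates <- function(visits, relapses, baseline_edss,
                                    direction, onset_day, window,
                                    confirmation_days = 180,
                                    exclusion_days = 30) {
  v <- visits[visits$day > window[1] & visits$day <= window[2], ]
  v <- v[order(v$day), ]
  step <- if (direction == "worsening") {
    if (baseline_edss == 0) 1.5 else if (baseline_edss <= 5.5) 1.0 else 0.5
  } else {
    if (baseline_edss < 1.5) return(FALSE)
    if (baseline_edss <= 1.5) 1.5 else if (baseline_edss <= 6.0) 1.0 else 0.5
  }
  meets <- if (direction == "worsening") v$edss - baseline_edss >= step - 1e-9
           else baseline_edss - v$edss >= step - 1e-9
  k <- which(v$day == onset_day)
  if (!length(k) || !meets[k[1]]) return(FALSE)
  k <- k[1]
  # a confirming visit must exist with all intermediate visits at threshold
  for (j in seq(k, nrow(v))) {
    if (!meets[j]) return(FALSE)
    if (v$day[j] >= onset_day + confirmation_days) {
      excl <- direction == "worsening" && length(relapses) &&
        any(v$day[j] > relapses & v$day[j] <= relapses + exclusion_days)
      if (!excl) return(TRUE)
    }
  }
  FALSE
}
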