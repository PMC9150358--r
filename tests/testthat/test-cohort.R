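# Index-episode selection, eligibility criteria and baseline derivation.

tx_row <- function(id, drug, start, end) {
  data.frame(patient_id = id, drug = drug, start_date = start, end_date = end)
}

test_that("index selection applies the 3-month minimum and earliest-episode rule", {
  # single qualifying episode after availability
  idx <- select_index_episode(tx_row(1, "natalizumab", 100, 220))
  expect_equal(nrow(idx), 1)
  expect_equal(idx$index_day, 100)
  expect_equal(as.character(idx$arm), "treated")

  # an 80-day episode does not qualify; the later 200-day episode does
  tr <- rbind(tx_row(1, "fingolimod", 50, 130),
              tx_row(1, "fingolimod", 300, 500))
  idx <- select_index_episode(tr)
  expect_equal(idx$index_day, 300)

  # open-ended episode qualifies only when observed >= 90 days
  tr <- tx_row(1, "natalizumab", 100, NA)
  idx <- select_index_episode(tr, last_record = data.frame(patient_id = 1,
                                                           last_record = 150))
  expect_equal(nrow(idx), 0)
  idx <- select_index_episode(tr, last_record = data.frame(patient_id = 1,
                                                           last_record = 250))
  expect_equal(idx$index_day, 100)

  # episodes before availability are skipped unless allow_pre_era
  tr <- tx_row(1, "natalizumab", -400, -100)
  expect_equal(nrow(select_index_episode(tr)), 0)
  idx <- select_index_episode(tr, allow_pre_era = TRUE)
  expect_equal(idx$index_day, -400)
})

test_that("prior exposure to an excluded therapy disqualifies the patient", {
  tr <- rbind(tx_row(1, "mitoxantrone", -600, -400),
              tx_row(1, "natalizumab", 100, 400),
              tx_row(2, "natalizumab", 100, 400))
  idx <- select_index_episode(tr)
  expect_equal(idx$patient_id, 2)
  excl <- attr(idx, "excluded")
  expect_equal(excl$patient_id, 1)
})

test_that("overlapping same-drug episodes are merged with a warning", {
  tr <- rbind(tx_row(1, "natalizumab", 100, 200),
              tx_row(1, "natalizumab", 150, 400))
  expect_warning(idx <- select_index_episode(tr), "overlap")
  expect_equal(idx$index_day, 100)
  expect_equal(idx$episode_end, 400)
})

mini_registry <- function(visit_days, relapse_days = numeric(),
                          visit_edss = NULL, index = 0, episode_end = 500) {
  pa <- data.frame(patient_id = 1, sex = "F", birth_year = 1980,
                   onset_date = -2000, country = "AU", source = "MSBase")
  if (is.null(visit_edss)) visit_edss <- rep(2.0, length(visit_days))
  vi <- data.frame(patient_id = 1, date = visit_days, edss = visit_edss)
  re <- data.frame(patient_id = rep(1, length(relapse_days)),
                   date = relapse_days)
  tr <- data.frame(patient_id = 1, drug = "natalizumab",
                   start_date = index, end_date = episode_end)
  reg <- registry_tables(pa, vi, re, tr)
  idx <- select_index_episode(reg$treatments,
                              last_record = last_record_table(reg))
  list(reg = reg, idx = idx)
}

test_that("eligibility requires baseline visit, post-visit span, on-treatment visit", {
  # baseline at day -10, post visits at 30 and 240 (on treatment): eligible
  m <- mini_registry(c(-10, 30, 240))
  el <- apply_eligibility(m$reg, m$idx)
  expect_equal(el$report$n_eligible, 1)

  # no pre-index EDSS within the 183-day window: criterion (a)
  m <- mini_registry(c(-300, 30, 240))
  el <- apply_eligibility(m$reg, m$idx)
  expect_equal(el$report$n_eligible, 0)
  expect_false(el$report$per_patient$has_baseline_edss)

  # post visits only 90 days apart: criterion (b)
  m <- mini_registry(c(-10, 30, 120))
  el <- apply_eligibility(m$reg, m$idx)
  expect_equal(el$report$n_eligible, 0)
  expect_false(el$report$per_patient$has_two_post_visits)

  # no visit during the episode: criterion (c)
  m <- mini_registry(c(-10, 450, 700), episode_end = 120)
  el <- apply_eligibility(m$reg, m$idx)
  expect_equal(el$report$n_eligible, 0)
  expect_false(el$report$per_patient$has_on_treatment_visit)

  # eligibility is the conjunction of the three criteria
  pp <- el$report$per_patient
  expect_equal(pp$eligible, pp$has_baseline_edss & pp$has_two_post_visits &
                 pp$has_on_treatment_visit)
})

test_that("baseline derivation windows relapse counts and picks the latest EDSS", {
  pa <- data.frame(patient_id = 1, sex = "M", birth_year = 1975,
                   onset_date = -3652, country = "DK", source = "DMSR")
  vi <- data.frame(patient_id = 1, date = c(-200, -50, 100, 300),
                   edss = c(3.0, 2.5, 2.5, 2.5))
  re <- data.frame(patient_id = rep(1, 3), date = c(-400, -300, -30))
  tr <- data.frame(patient_id = 1, drug = "fingolimod", start_date = 0,
                   end_date = 400)
  bl <- derive_baseline(pa, vi, re, tr, index_date = 0)
  expect_equal(bl$n_relapses_prior_12m, 2)        # -400 outside the window
  expect_equal(bl$baseline_edss, 2.5)             # day -50 beats day -200
  expect_equal(bl$baseline_edss_day, -50)
  expect_equal(as.character(bl$arm), "control")
  expect_equal(bl$ms_duration, 3652 / 365.25)
  expect_equal(as.character(bl$prior_activity), "relapse")

  # no relapse, no worsening: activity "none"
  bl2 <- derive_baseline(pa, vi, re[0, ], tr, index_date = 0)
  expect_equal(as.character(bl2$prior_activity), "none")
  expect_equal(bl2$n_relapses_prior_12m, 0)

  # a confirmed pre-index worsening is picked up from the visit history
  vi3 <- data.frame(patient_id = 1, date = c(-350, -250, -50, 100, 300),
                    edss = c(2.0, 3.0, 3.0, 3.0, 3.0))
  bl3 <- derive_baseline(pa, vi3, re[0, ], tr, index_date = 0)
  expect_equal(as.character(bl3$prior_activity), "worsening")

  # missing onset date is rejected
  pa_bad <- pa; pa_bad$onset_date <- NA
  expect_error(derive_baseline(pa_bad, vi, re, tr, 0), "onset date")
})

test_that("generator output passes eligibility in full and round-trips the truth", {
  fx <- small_cohort()
  expect_equal(fx$report$n_eligible, nrow(fx$sr$truth))
  expect_equal(anyDuplicated(fx$bl$patient_id), 0)
  m <- merge(fx$bl, fx$sr$truth, by = "patient_id")
  expect_equal(as.character(m$arm.x), as.character(m$arm.y))
  expect_equal(m$baseline_edss.x, m$baseline_edss.y)
  expect_equal(m$n_relapses_prior_12m.x, m$n_relapses_prior_12m.y)
  expect_equal(m$n_prior_treatments.x, m$n_prior_treatments.y)
  expect_equal(as.character(m$prior_activity.x),
               as.character(m$prior_activity.y))
  expect_equal(m$ms_duration.x, m$ms_duration.y, tolerance = 0.01)
  expect_equal(m$age.x, m$age.y, tolerance = 0.6)
})
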