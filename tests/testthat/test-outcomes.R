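# Outcome definitions: relapse counting, first relapse, the confirmed
# EDSS-change detector, visit density and reverse Kaplan-Meier follow-up.

test_that("relapse counts use the half-open window with exposure", {
  expect_equal(count_relapses(numeric(), c(0, 365)),
               list(count = 0L, exposure_days = 365))
  r <- count_relapses(c(10, 100, 400), c(0, 365))
  expect_equal(r$count, 2L)
  expect_equal(r$exposure_days, 365)
  # an onset on the index day belongs to baseline history
  expect_equal(count_relapses(0, c(0, 365))$count, 0L)
  # the right endpoint is closed
  expect_equal(count_relapses(365, c(0, 365))$count, 1L)
})

test_that("time to first relapse takes the earliest in-window onset", {
  r <- time_to_first_relapse(42, c(0, 365))
  expect_equal(r$event, 1L)
  expect_equal(r$event_day, 42)
  r2 <- time_to_first_relapse(400, c(0, 365))
  expect_equal(r2$event, 0L)
  expect_equal(r2$followup_days, 365)
  r3 <- time_to_first_relapse(c(60, 42), c(0, 365))
  expect_equal(r3$event_day, 42)
})

test_that("confirmed worsening follows the threshold/confirmation/exclusion rules", {
  vis <- data.frame(day = c(90, 180, 300), edss = c(3, 3, 3))
  # confirmed at day 300 (210 >= 180 days, all intermediate at threshold)
  r <- detect_confirmed_change(vis, baseline_edss = 2.0,
                               direction = "worsening", window = c(0, 365))
  expect_equal(r$event, 1L)
  expect_equal(r$event_day, 90)

  # baseline 0 needs +1.5 steps: sustained 1.0 is no event
  vis0 <- data.frame(day = c(90, 180, 300), edss = c(1, 1, 1))
  r0 <- detect_confirmed_change(vis0, baseline_edss = 0,
                                direction = "worsening", window = c(0, 365))
  expect_equal(r0$event, 0L)

  # a relapse 10 days before the only confirming visit blocks confirmation
  vis1 <- data.frame(day = c(90, 300), edss = c(3, 3))
  r1 <- detect_confirmed_change(vis1, relapses = 290, baseline_edss = 2.0,
                                direction = "worsening", window = c(0, 365))
  expect_equal(r1$event, 0L)
  # without the relapse the same history confirms
  r1b <- detect_confirmed_change(vis1, baseline_edss = 2.0,
                                 direction = "worsening", window = c(0, 365))
  expect_equal(r1b$event, 1L)
  # a later clean visit can still confirm past an excluded one
  vis2 <- data.frame(day = c(90, 300, 400), edss = c(3, 3, 3))
  r2 <- detect_confirmed_change(vis2, relapses = 290, baseline_edss = 2.0,
                                direction = "worsening", window = c(0, 500))
  expect_equal(r2$event, 1L)
  expect_equal(r2$event_day, 90)

  # a dip below threshold discards the candidate; scanning resumes after it
  vis3 <- data.frame(day = c(60, 150, 240, 430, 500),
                     edss = c(3, 2, 3, 3, 3))
  r3 <- detect_confirmed_change(vis3, baseline_edss = 2.0,
                                direction = "worsening", window = c(0, 600))
  expect_equal(r3$event, 1L)
  expect_equal(r3$event_day, 240)

  # transient relapse bump alone never confirms
  vis4 <- data.frame(day = c(80, 170, 260), edss = c(3, 2, 2))
  r4 <- detect_confirmed_change(vis4, relapses = 70, baseline_edss = 2.0,
                                direction = "worsening", window = c(0, 365))
  expect_equal(r4$event, 0L)

  expect_error(detect_confirmed_change(
    data.frame(day = 90, edss = 2.3), baseline_edss = 2.0,
    direction = "worsening", window = c(0, 365)), "half-point grid")
})

test_that("improvement uses its own thresholds and is undefined below EDSS 1.5", {
  vis <- data.frame(day = c(90, 300), edss = c(2, 2))
  r <- detect_confirmed_change(vis, baseline_edss = 3.0,
                               direction = "improvement", window = c(0, 365))
  expect_equal(r$event, 1L)
  expect_equal(r$event_day, 90)
  # baseline 1.0: structurally censored
  r2 <- detect_confirmed_change(vis, baseline_edss = 1.0,
                                direction = "improvement", window = c(0, 365))
  expect_equal(r2$event, 0L)
  expect_true(r2$structural)
  # improvement confirmation has no relapse clause
  r3 <- detect_confirmed_change(vis, relapses = 290, baseline_edss = 3.0,
                                direction = "improvement", window = c(0, 365))
  expect_equal(r3$event, 1L)
})

test_that("shrinking the window never creates an event and detection is idempotent", {
  set.seed(77)
  grid_vals <- seq(0, 10, 0.5)
  for (i in 1:100) {
    nv <- sample(3:12, 1)
    vis <- data.frame(day = sort(sample(1:900, nv)),
                      edss = sample(grid_vals, nv, TRUE))
    rel <- sort(sample(1:900, sample(0:3, 1)))
    b <- sample(grid_vals, 1)
    dir <- sample(c("worsening", "improvement"), 1)
    full <- detect_confirmed_change(vis, rel, b, dir, window = c(0, 900))
    again <- detect_confirmed_change(vis, rel, b, dir, window = c(0, 900))
    expect_identical(full, again)
    short <- detect_confirmed_change(vis, rel, b, dir, window = c(0, 450))
    if (short$event == 1L) {
      expect_equal(full$event, 1L)
      expect_lte(short$event_day, full$event_day)
    }
    if (full$event == 1L) {
      expect_true(verify_event_predicates(vis, rel, b, dir, full$event_day,
                                          c(0, 900)))
      expect_lte(full$event_day, full$followup_days)
    }
  }
})

test_that("visit density is an annualized rate and rejects empty windows", {
  expect_equal(visit_density(c(10, 100, 200, 300), c(0, 365.25)), 4)
  expect_equal(visit_density(numeric(), c(0, 365.25)), 0)
  expect_equal(visit_density(seq(50, 700, length.out = 6), c(0, 730.5)), 3)
  expect_error(visit_density(c(10), c(0, 0)), "zero-length")
})

test_that("reverse Kaplan-Meier median matches the hand-worked table", {
  # mixed 6 follow-ups, hand KM with flipped indicator: S(400)=8/15>0.5,
  # S(500)=4/15<0.5 -> median 500
  r <- reverse_km_median(c(100, 200, 300, 400, 500, 600),
                         c(1, 0, 1, 0, 0, 1))
  expect_equal(r$median, 500)
  # all censored for the outcome: ordinary median of follow-up
  r2 <- reverse_km_median(c(10, 20, 30), c(0, 0, 0))
  expect_equal(r2$median, 20)
  # everyone has the outcome: median not reached
  r3 <- reverse_km_median(c(10, 20, 30), c(1, 1, 1))
  expect_true(is.na(r3$median))
})

test_that("detector sensitivity approaches one on injected latent events and bumps alone never trigger", {
  cfg <- simulation_config(
    n_patients = 600, seed = 31,
    true_effects = list(irr_relapse = 1, hr_relapse = 1, hr_worsening = 1,
                        hr_improvement = 1),
    outcome_params = list(base_relapse_rate = 0.4,
                          log_rate_per_prior_relapse = 0,
                          log_rate_edss = c(0, 0, 0), frailty_var = 0,
                          worsening_rate = 0.25, improvement_rate = 0,
                          effect_stops_at_discontinuation = TRUE,
                          relapse_bump = 1, bump_days = 30))
  sr <- generate_registry(cfg)
  fx <- run_cohort_ps(sr)
  win <- censor_itt(fx$bl)
  rec <- derive_outcome_records(sr$registry, fx$bl, win, "worsening")
  tru <- sr$truth[, c("patient_id", "t_worsening", "followup_days")]
  data.table::setnames(tru, "followup_days", "fu_true")
  m <- merge(rec, tru, by = "patient_id")
  # latent events with at least 180 days of visits left to confirm
  detectable <- m$t_worsening <= m$fu_true - 270
  expect_gt(mean(m$event[detectable] == 1), 0.95)
  # no latent event: transient relapse bumps must never produce one
  expect_equal(sum(m$event[m$t_worsening > m$fu_true]), 0)
  # event days never exceed follow-up
  expect_true(all(m$event_day[m$event == 1] <= m$followup_days[m$event == 1]))
})
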