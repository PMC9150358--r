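# Synthetic registry generator: determinism, referential integrity,
# assignment law, relapse/EDSS/discontinuation processes.

test_that("generation is deterministic given config and seed", {
  cfg <- simulation_config(n_patients = 100, seed = 1)
  a <- generate_registry(cfg)
  b <- generate_registry(cfg)
  expect_identical(a$registry$patients, b$registry$patients)
  expect_identical(a$registry$visits, b$registry$visits)
  expect_identical(a$registry$relapses, b$registry$relapses)
  expect_identical(a$registry$treatments, b$registry$treatments)
  expect_identical(a$truth, b$truth)
  d <- generate_registry(simulation_config(n_patients = 100, seed = 2))
  expect_false(identical(a$truth$true_ps, d$truth$true_ps))
})

test_that("tables satisfy referential integrity and study-drug coverage", {
  sr <- small_cohort()$sr
  reg <- sr$registry
  ids <- reg$patients$patient_id
  expect_true(all(reg$visits$patient_id %in% ids))
  expect_true(all(reg$relapses$patient_id %in% ids))
  expect_true(all(reg$treatments$patient_id %in% ids))
  study <- reg$treatments[drug %in% c("natalizumab", "fingolimod")]
  expect_setequal(unique(study$patient_id), ids)
})

test_that("era switch controls pre-availability index episodes", {
  cfg <- simulation_config(n_patients = 300, seed = 3,
                           era = list(enabled = FALSE, pre_era_fraction = 0,
                                      pre_era_span = 1460,
                                      pre_era_rate_multiplier = 1.6))
  sr <- generate_registry(cfg)
  study <- sr$registry$treatments[drug %in% c("natalizumab", "fingolimod")]
  expect_true(all(study$start_date >= 0))

  cfg2 <- simulation_config(n_patients = 300, seed = 3,
                            era = list(enabled = TRUE, pre_era_fraction = 0.3,
                                       pre_era_span = 1460,
                                       pre_era_rate_multiplier = 1.6))
  sr2 <- generate_registry(cfg2)
  pre <- sr2$truth[pre_era == TRUE]
  expect_gt(nrow(pre), 0)
  expect_true(all(pre$index_day < 0))
  expect_true(all(pre$arm == "treated"))
  expect_true(all(pre$true_ps == 1))
})

test_that("assignment model follows the inverse-logit law", {
  cov1 <- data.frame(sex = "F", age = 38, ms_duration = 7,
                     baseline_edss = 1.0, n_relapses_prior_12m = 0,
                     n_prior_treatments = 0, prior_activity = "none")
  zero <- c(intercept = 0, sexM = 0, age = 0, ms_duration = 0,
            edss_2_35 = 0, edss_4p = 0, rel_1 = 0, rel_2 = 0, rel_3p = 0,
            tx_1 = 0, tx_2 = 0, tx_3p = 0, act_worsening = 0,
            act_relapse = 0, act_both = 0)
  expect_equal(assign_treatment(cov1, zero)$true_ps, 0.5)
  # the study's 39% treated marginal as a calibration anchor
  anchor <- zero; anchor["intercept"] <- -0.447
  expect_equal(assign_treatment(cov1, anchor)$true_ps, 0.39, tolerance = 1e-3)
  # pre-era patients can only start the treated drug
  res <- assign_treatment(cov1[rep(1, 50), ], zero, era_flag = TRUE)
  expect_true(all(res$arm == "treated"))
  expect_true(all(res$true_ps == 1))
  expect_error(assign_treatment(cov1[, -1], zero), "missing covariate")
  expect_error(assign_treatment(cov1, zero[-1]), "missing coefficient")
})

test_that("refitting the assignment model on generated data recovers the coefficients", {
  fx <- big_cohort()
  truth <- fx$sr$truth
  cfg <- simulation_config(n_patients = 5000, seed = 42)
  # fit on true covariates to isolate the assignment law
  cov <- truth[, .(sex = fx$sr$registry$patients$sex,
                   age, ms_duration, baseline_edss,
                   n_relapses_prior_12m, n_prior_treatments, prior_activity)]
  dat <- data.frame(
    treated = truth$arm == "treated",
    sexM = cov$sex == "M",
    age = cov$age - 38, msd = cov$ms_duration - 7,
    e2 = cov$baseline_edss >= 2 & cov$baseline_edss < 4,
    e4 = cov$baseline_edss >= 4,
    r1 = cov$n_relapses_prior_12m == 1, r2 = cov$n_relapses_prior_12m == 2,
    r3 = cov$n_relapses_prior_12m >= 3,
    t1 = cov$n_prior_treatments == 1, t2 = cov$n_prior_treatments == 2,
    t3 = cov$n_prior_treatments >= 3,
    aw = cov$prior_activity == "worsening",
    ab = cov$prior_activity == "relapse and worsening",
    country = fx$sr$registry$patients$country
  )
  fit <- glm(treated ~ ., data = dat, family = binomial())
  co <- coef(fit); se <- sqrt(diag(vcov(fit)))
  gen <- cfg$ps_coefficients
  expected <- c("(Intercept)" = unname(gen["intercept"]),
                sexMTRUE = unname(gen["sexM"]), age = unname(gen["age"]),
                msd = unname(gen["ms_duration"]),
                e2TRUE = unname(gen["edss_2_35"]),
                e4TRUE = unname(gen["edss_4p"]),
                r1TRUE = unname(gen["rel_1"]), r2TRUE = unname(gen["rel_2"]),
                r3TRUE = unname(gen["rel_3p"]),
                t1TRUE = unname(gen["tx_1"]), t2TRUE = unname(gen["tx_2"]),
                t3TRUE = unname(gen["tx_3p"]),
                awTRUE = unname(gen["act_worsening"]),
                abTRUE = unname(gen["act_both"]),
                countryDK = 0.4, countryFR = -0.3)
  z <- abs(co[names(expected)] - expected) / se[names(expected)]
  # confounding coefficients recovered; allow one coefficient of the family
  # to sit between 2 and 3 standard errors by sampling variation
  expect_true(all(z < 3))
  expect_lte(sum(z > 2), 1)
  # direction of the confounding by indication
  expect_gt(co[["e4TRUE"]], 0)
  expect_gt(co[["r3TRUE"]], 0)
  expect_lt(co[["t1TRUE"]], 0)
})

test_that("relapse process follows the configured rates", {
  expect_error(simulate_relapse_process(0, 0.5), "window_days > 0")
  set.seed(1)
  expect_identical(simulate_relapse_process(365, 0), numeric())
  r <- simulate_relapse_process(3652.5, 0.5)
  expect_true(all(r > 0 & r <= 3652.5))
  expect_false(is.unsorted(r))

  # 10,000 patient-years per arm at rate 0.5/yr, IRR 0.7
  set.seed(99)
  py <- 5
  n <- 2000
  ev_c <- sum(vapply(seq_len(n), function(i)
    length(simulate_relapse_process(py * 365.25, 0.5)), numeric(1)))
  ev_t <- sum(vapply(seq_len(n), function(i)
    length(simulate_relapse_process(py * 365.25, 0.5, irr = 0.7,
                                    treated = TRUE)), numeric(1)))
  ratio <- (ev_t / (n * py)) / (ev_c / (n * py))
  expect_true(abs(ratio - 0.7) < 0.05)

  # null effect: pooled empirical rates equal within Monte-Carlo error
  set.seed(100)
  ev_t1 <- sum(vapply(seq_len(n), function(i)
    length(simulate_relapse_process(py * 365.25, 0.5, irr = 1,
                                    treated = TRUE)), numeric(1)))
  expect_true(abs(ev_t1 / ev_c - 1) < 0.1)
})

test_that("EDSS trajectories respect the grid, latent events and bumps", {
  expect_error(simulate_edss_trajectory(2.3, c(30, 60)), "half-point grid")
  flat <- simulate_edss_trajectory(2.0, c(30, 200, 400),
                                   worsening_day = Inf, improvement_day = Inf)
  expect_equal(flat$edss, rep(2.0, 3))
  forced <- simulate_edss_trajectory(2.0, c(50, 100, 250, 400),
                                     worsening_day = 100,
                                     improvement_day = Inf)
  expect_equal(forced$edss, c(2.0, 3.0, 3.0, 3.0))
  expect_true(all(forced$edss[forced$day >= 100] >= 3.0))
  # transient bump within 30 days after a relapse
  bumped <- simulate_edss_trajectory(2.0, c(50, 100, 150),
                                     relapse_days = 90,
                                     worsening_day = Inf,
                                     improvement_day = Inf)
  expect_equal(bumped$edss, c(2.0, 3.0, 2.0))
})

test_that("latent worsening times reproduce the configured hazard ratio", {
  cfg <- simulation_config(
    n_patients = 4000, seed = 5,
    true_effects = list(irr_relapse = 1, hr_relapse = 1, hr_worsening = 0.5,
                        hr_improvement = 1),
    outcome_params = list(base_relapse_rate = 0.3,
                          log_rate_per_prior_relapse = 0, log_rate_edss = c(0, 0, 0),
                          frailty_var = 0, worsening_rate = 0.15,
                          improvement_rate = 0,
                          effect_stops_at_discontinuation = TRUE,
                          relapse_bump = 1, bump_days = 30))
  tr <- generate_registry(cfg)$truth
  time <- pmin(tr$t_worsening, tr$followup_days)
  ev <- as.integer(tr$t_worsening <= tr$followup_days)
  fit <- survival::coxph(survival::Surv(time, ev) ~ arm, data = tr)
  hr <- exp(coef(fit)[[1]])
  ci <- exp(confint(fit))
  expect_true(hr > 0.4 && hr < 0.62)
  expect_true(ci[1] < 0.5 && ci[2] > 0.5)
})

test_that("discontinuation hazard couples to the relapse history as configured", {
  expect_identical(simulate_discontinuation(numeric(), hazard = 0), NA_real_)
  set.seed(21)
  n <- 2000
  nrel <- rpois(n, 2)
  hist <- lapply(nrel, function(k) sort(runif(k, 0, 1500)))
  d0 <- vapply(hist, function(h)
    simulate_discontinuation(h, hazard = 0.4, dependence = 0,
                             horizon = Inf), numeric(1))
  expect_lt(abs(cor(d0, nrel)), 0.07)
  d1 <- vapply(hist, function(h)
    simulate_discontinuation(h, hazard = 0.4, dependence = 0.8,
                             horizon = Inf), numeric(1))
  w <- wilcox.test(d1[nrel >= 2], d1[nrel == 0], alternative = "less")
  expect_lt(w$p.value, 0.01)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(simulation_config(n_patients = 1), "n_patients")
  expect_error(simulation_config(true_effects = list(
    irr_relapse = -1, hr_relapse = 1, hr_worsening = 1, hr_improvement = 1)),
    "irr_relapse")
  bad_countries <- data.frame(label = "A", intercept = 0, prop = 0.5,
                              source = "X")
  expect_error(simulation_config(countries = bad_countries), "countries")
  expect_error(simulation_config(era = list(enabled = TRUE,
                                            pre_era_fraction = 1.4,
                                            pre_era_span = 100,
                                            pre_era_rate_multiplier = 1)),
               "pre_era_fraction")
})

test_that("registry round-trips through CSV serialization", {
  sr <- generate_registry(simulation_config(n_patients = 60, seed = 13))
  dir <- withr::local_tempdir()
  write_registry(sr$registry, dir, truth = sr$truth)
  back <- read_registry(dir)
  expect_equal(as.data.frame(back$patients), as.data.frame(sr$registry$patients))
  expect_equal(as.data.frame(back$visits), as.data.frame(sr$registry$visits))
  expect_equal(as.data.frame(back$relapses), as.data.frame(sr$registry$relapses))
  expect_equal(as.data.frame(back$treatments),
               as.data.frame(sr$registry$treatments))
})
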