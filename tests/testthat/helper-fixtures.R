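# Shared fixtures, built once per test run and cached across files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# full pipeline on one registry: cohort -> PS -> scores
run_cohort_ps <- function(sr, use_random_country = FALSE) {
  reg <- sr$registry
  idx <- select_index_episode(reg$treatments,
                              availability_day = reg$meta$availability_day,
                              last_record = last_record_table(reg))
  el <- apply_eligibility(reg, idx)
  psm <- fit_ps_model(el$baseline, use_random_country = use_random_country)
  psr <- predict_ps(psm, el$baseline)
  list(sr = sr, reg = reg, idx = idx, bl = el$baseline, report = el$report,
       psm = psm, psr = psr)
}

# 5000-patient confounded cohort with the default true effects
big_cohort <- function() {
  fixture("big", function() {
    sr <- generate_registry(simulation_config(n_patients = 5000, seed = 42))
    run_cohort_ps(sr)
  })
}

# small registry for structural tests
small_cohort <- function() {
  fixture("small", function() {
    sr <- generate_registry(simulation_config(n_patients = 500, seed = 7))
    run_cohort_ps(sr)
  })
}

# minimal hand-built baseline table for formula-level tests
make_baseline <- function(n, arm, age = 40, ms_duration = 6,
                          baseline_edss = 2.5, sex = "F",
                          n_relapses_prior_12m = 1, n_prior_treatments = 1,
                          prior_activity = "relapse", country = "AU") {
  data.frame(
    patient_id = seq_len(n),
    arm = factor(arm, levels = c("control", "treated")),
    sex = rep_len(sex, n),
    age = rep_len(age, n),
    ms_duration = rep_len(ms_duration, n),
    baseline_edss = rep_len(baseline_edss, n),
    n_relapses_prior_12m = rep_len(n_relapses_prior_12m, n),
    n_prior_treatments = rep_len(n_prior_treatments, n),
    prior_activity = rep_len(prior_activity, n),
    country = rep_len(country, n),
    stringsAsFactors = FALSE
  )
}

# hand-built ps_result-like table
make_ps <- function(ps_treated, ps_control) {
  data.table::data.table(
    patient_id = seq_len(length(ps_treated) + length(ps_control)),
    arm = factor(rep(c("treated", "control"),
                     c(length(ps_treated), length(ps_control))),
                 levels = c("control", "treated")),
    ps = c(ps_treated, ps_control),
    lp = qlogis(c(ps_treated, ps_control))
  )
}
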