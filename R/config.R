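#' Configuration for the synthetic registry generator
#'
#' Builds and validates the full set of parameters that drive
#' [generate_registry()]. The defaults describe a two-treatment
#' relapsing-remitting MS cohort with confounding by indication: more active
#' and more disabled patients are preferentially assigned the index ("treated")
#' therapy, relapse rates depend on the same baseline covariates, treatment
#' discontinuation is informative (its hazard rises with on-treatment
#' relapses), and an optional pre-availability era in which only the treated
#' drug could be prescribed (a structural positivity violation).
#'
#' All dates are integer day offsets from the availability date of the control
#' drug (day 0); calendar formatting happens only at I/O ([write_registry()]).
#'
#' @param n_patients Number of patients to simulate (>= 2).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @param countries `data.frame` with columns `label`, `intercept` (country
#'   random-intercept value on the assignment log-odds scale), `prop`
#'   (population share, must sum to 1) and `source` (registry name written to
#'   the patients table).
#' @param covariate_params List of baseline covariate distribution parameters;
#'   see the default for the full field set.
#' @param ps_coefficients Named numeric vector of log-odds coefficients of the
#'   treatment-assignment model (see [assign_treatment()] for the coding).
#' @param true_effects List with elements `irr_relapse`, `hr_relapse`,
#'   `hr_worsening`, `hr_improvement`: treated-vs-control ratios, all > 0.
#' @param outcome_params List controlling the relapse and EDSS processes:
#'   baseline relapse rate (per year), log-rate covariate effects, gamma
#'   frailty variance, latent worsening/improvement hazards (per year),
#'   whether the relapse effect stops at discontinuation, and the transient
#'   post-relapse EDSS bump (size in EDSS steps, duration in days).
#' @param discontinuation List with per-arm discontinuation hazards (per year)
#'   and `dependence`, the increase in log-hazard per on-treatment relapse
#'   (0 means non-informative censoring).
#' @param visit_schedule List with `mean_gap` (days) and `jitter` (SD, days)
#'   of the post-baseline EDSS visit schedule.
#' @param followup List with `meanlog`/`sdlog` of the lognormal per-patient
#'   record-availability window after the index date (days), truncated to
#'   `min_days`/`max_days`; defaults give a median near 3.1 years with
#'   interquartile range about 2.0-4.6 years.
#' @param era List with `enabled`, `pre_era_fraction` (share of patients
#'   indexed before day 0), `pre_era_span` (days before availability over
#'   which pre-era index dates spread), `pre_era_rate_multiplier`
#'   (unmeasured relapse-rate multiplier of pre-era patients, the source of
#'   bias when positivity is violated), and `edss_band_probs` /
#'   `relapse_probs` (baseline covariate distributions of the pre-era
#'   subpopulation — historically the treated drug went to more active,
#'   more disabled patients, the confounded-inclusion feature that piles
#'   their refitted scores near 1 with a left tail).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 2000,
    seed = 1L,
    countries = data.frame(
      label = c("AU", "DK", "FR"),
      intercept = c(0, 0.4, -0.3),
      prop = c(0.64, 0.28, 0.08),
      source = c("MSBase", "DMSR", "OFSEP"),
      stringsAsFactors = FALSE
    ),
    covariate_params = list(
      p_female = 0.72,
      age_mean = 37.7, age_sd = 10.5, age_range = c(18, 70),
      msd_meanlog = log(6.9), msd_sdlog = 0.9, msd_range = c(0.2, 40),
      edss_band_probs = c(0.30, 0.46, 0.24),
      relapse_probs = c(0.36, 0.39, 0.19, 0.045, 0.015),
      prior_tx_probs = c(0.16, 0.50, 0.23, 0.08, 0.03),
      p_worsening_given_relapse = 0.344,
      p_worsening_given_no_relapse = 0.222
    ),
    ps_coefficients = c(
      intercept = -1.40,
      sexM = 0.05,
      age = -0.015,
      ms_duration = -0.02,
      edss_2_35 = 0.55, edss_4p = 0.85,
      rel_1 = 0.45, rel_2 = 0.85, rel_3p = 1.15,
      tx_1 = -0.30, tx_2 = -0.20, tx_3p = -0.10,
      # act_relapse is aliased with the relapse-count bands (relapse
      # activity occurs iff the count is >= 1) and defaults to 0 so the
      # generating model stays identifiable under the analysis coding
      act_worsening = 0.30, act_relapse = 0, act_both = 0.35
    ),
    true_effects = list(irr_relapse = 0.7, hr_relapse = 0.7,
                        hr_worsening = 1.0, hr_improvement = 1.3),
    outcome_params = list(
      base_relapse_rate = 0.40,
      log_rate_per_prior_relapse = 0.15,
      log_rate_edss = c(0, 0.05, 0.10),
      # kept modest so marginal time-to-event ratios stay within ~2% of the
      # conditional generating ratios (hazard ratios do not collapse over
      # strong frailty) while counts remain genuinely overdispersed
      frailty_var = 0.15,
      worsening_rate = 0.10,
      improvement_rate = 0.10,
      effect_stops_at_discontinuation = TRUE,
      relapse_bump = 1.0,
      bump_days = 30
    ),
    discontinuation = list(rate_treated = 0.30, rate_control = 0.30,
                           dependence = 0.30),
    visit_schedule = list(mean_gap = 90, jitter = 20),
    # lognormal record availability: median ~3.1 years, IQR ~2.0-4.6
    followup = list(meanlog = log(3.1 * 365.25), sdlog = 0.6,
                    min_days = 550, max_days = 4000),
    era = list(enabled = FALSE, pre_era_fraction = 0.25,
               pre_era_span = 1460, pre_era_rate_multiplier = 1.6,
               edss_band_probs = c(0.10, 0.35, 0.55),
               relapse_probs = c(0.10, 0.30, 0.35, 0.15, 0.10))) {
  # partially specified sub-lists are merged over their defaults
  merge_dflt <- function(name, value) {
    d <- eval(formals(simulation_config)[[name]])
    utils::modifyList(d, value)
  }
  cfg <- list(
    n_patients = n_patients, seed = as.integer(seed), countries = countries,
    covariate_params = merge_dflt("covariate_params", covariate_params),
    ps_coefficients = ps_coefficients,
    true_effects = merge_dflt("true_effects", true_effects),
    outcome_params = merge_dflt("outcome_params", outcome_params),
    discontinuation = merge_dflt("discontinuation", discontinuation),
    visit_schedule = merge_dflt("visit_schedule", visit_schedule),
    followup = merge_dflt("followup", followup),
    era = merge_dflt("era", era)
  )
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [simulation_config()] object and
#' stops with an error naming the offending field.
#'
#' @param config A `simulation_config` object (or plain list with the same
#'   fields).
#' @return The configuration, invisibly, if valid.
#' @export
validate_config <- function(config) {
  fail <- function(field, why) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(config$n_patients) || length(config$n_patients) != 1 ||
      config$n_patients < 2 || config$n_patients != round(config$n_patients))
    fail("n_patients", "must be an integer >= 2")
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
      !is.finite(config$seed))
    fail("seed", "must be a single finite number")
  co <- config$countries
  if (!is.data.frame(co) ||
      !all(c("label", "intercept", "prop", "source") %in% names(co)))
    fail("countries", "must be a data.frame with label/intercept/prop/source")
  if (abs(sum(co$prop) - 1) > 1e-8 || any(co$prop < 0))
    fail("countries", "proportions must be nonnegative and sum to 1")
  for (p in c("edss_band_probs", "relapse_probs", "prior_tx_probs")) {
    pr <- config$covariate_params[[p]]
    if (is.null(pr) || any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      fail(paste0("covariate_params$", p),
           "must be nonnegative proportions summing to 1")
  }
  te <- config$true_effects
  for (nm in c("irr_relapse", "hr_relapse", "hr_worsening", "hr_improvement")) {
    if (!is.numeric(te[[nm]]) || length(te[[nm]]) != 1 || te[[nm]] <= 0)
      fail(paste0("true_effects$", nm), "must be a positive ratio")
  }
  if (is.null(names(config$ps_coefficients)) ||
      !("intercept" %in% names(config$ps_coefficients)))
    fail("ps_coefficients", "must be a named vector including 'intercept'")
  di <- config$discontinuation
  if (any(c(di$rate_treated, di$rate_control) < 0))
    fail("discontinuation", "hazards must be nonnegative")
  if (config$visit_schedule$mean_gap <= 0)
    fail("visit_schedule$mean_gap", "must be positive")
  if (config$followup$min_days <= 0 ||
      config$followup$max_days < config$followup$min_days)
    fail("followup", "requires 0 < min_days <= max_days")
  if (!is.numeric(config$followup$meanlog) ||
      !is.numeric(config$followup$sdlog) || config$followup$sdlog < 0)
    fail("followup", "requires numeric meanlog and nonnegative sdlog")
  er <- config$era
  if (!is.logical(er$enabled))
    fail("era$enabled", "must be TRUE or FALSE")
  if (er$pre_era_fraction < 0 || er$pre_era_fraction > 1)
    fail("era$pre_era_fraction", "must lie in [0, 1]")
  for (p in c("edss_band_probs", "relapse_probs")) {
    pr <- er[[p]]
    if (is.null(pr) || any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      fail(paste0("era$", p), "must be nonnegative proportions summing to 1")
  }
  if (config$outcome_params$base_relapse_rate < 0)
    fail("outcome_params$base_relapse_rate", "must be nonnegative")
  if (config$outcome_params$frailty_var < 0)
    fail("outcome_params$frailty_var", "must be nonnegative")
  invisible(config)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  true effects: IRR(relapse)", x$true_effects$irr_relapse,
      "| HR(relapse)", x$true_effects$hr_relapse,
      "| HR(worsening)", x$true_effects$hr_worsening,
      "| HR(improvement)", x$true_effects$hr_improvement, "\n")
  cat("  era violation:", if (isTRUE(x$era$enabled))
    sprintf("enabled (%.0f%% pre-era)", 100 * x$era$pre_era_fraction)
    else "disabled", "\n")
  invisible(x)
}
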