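# Synthetic two-treatment registry generator.
#
# The generator inverts the analysis assumptions as a data-generating law:
# logistic treatment assignment on the baseline covariate set (confounding by
# indication), Poisson relapses with gamma frailty (negative binomial
# marginally) whose rate is scaled by the true incidence-rate ratio while on
# the treated drug, latent proportional-hazards EDSS worsening/improvement
# events expressed on the half-point grid, informative discontinuation whose
# hazard rises with on-treatment relapses, and an optional pre-availability
# era during which only the treated drug can be started.

# linear predictor of the assignment model; coding must mirror the
# propensity-module covariate bands (age/duration continuous, others banded)
.assignment_lp <- function(cov, coefficients) {
  req <- c("sex", "age", "ms_duration", "baseline_edss",
           "n_relapses_prior_12m", "n_prior_treatments", "prior_activity")
  miss <- setdiff(req, names(cov))
  if (length(miss))
    stop("assign_treatment: missing covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cf <- function(nm) {
    if (!nm %in% names(coefficients))
      stop("assign_treatment: missing coefficient '", nm, "'", call. = FALSE)
    coefficients[[nm]]
  }
  edss <- cov$baseline_edss
  nrel <- cov$n_relapses_prior_12m
  ntx <- cov$n_prior_treatments
  act <- as.character(cov$prior_activity)
  cf("intercept") +
    cf("sexM") * (cov$sex == "M") +
    cf("age") * (cov$age - 38) +
    cf("ms_duration") * (cov$ms_duration - 7) +
    cf("edss_2_35") * (edss >= 2 & edss < 4) +
    cf("edss_4p") * (edss >= 4) +
    cf("rel_1") * (nrel == 1) + cf("rel_2") * (nrel == 2) +
    cf("rel_3p") * (nrel >= 3) +
    cf("tx_1") * (ntx == 1) + cf("tx_2") * (ntx == 2) + cf("tx_3p") * (ntx >= 3) +
    cf("act_worsening") * (act == "worsening") +
    cf("act_relapse") * (act == "relapse") +
    cf("act_both") * (act == "relapse and worsening")
}

#' Simulate treatment assignment from baseline covariates
#'
#' Draws the treatment arm from the logistic assignment model that the
#' propensity-score analysis later tries to recover: the probability of
#' starting the treated drug is the inverse logit of a linear predictor over
#' sex, age, MS duration, baseline EDSS band, prior-relapse band,
#' prior-treatment band and prior clinical activity, plus a country intercept.
#' Patients flagged as pre-era (indexed before the control drug became
#' available) are assigned the treated drug with probability one and their
#' true propensity is recorded as 1 — the structural positivity violation.
#'
#' @param covariates `data.frame` with columns `sex` ("F"/"M"), `age`,
#'   `ms_duration` (years), `baseline_edss`, `n_relapses_prior_12m`,
#'   `n_prior_treatments`, `prior_activity` (one of "none", "worsening",
#'   "relapse", "relapse and worsening").
#' @param coefficients Named vector of log-odds coefficients (see
#'   [simulation_config()] for the term names).
#' @param country_intercept Per-patient country random-intercept value
#'   (recycled).
#' @param era_flag Logical (recycled): TRUE marks pre-availability patients.
#' @return `data.frame` with columns `arm` (factor control/treated) and
#'   `true_ps`.
#' @export
assign_treatment <- function(covariates, coefficients, country_intercept = 0,
                             era_flag = FALSE) {
  n <- nrow(covariates)
  lp <- .assignment_lp(covariates, coefficients) + rep_len(country_intercept, n)
  ps <- plogis(lp)
  era_flag <- rep_len(as.logical(era_flag), n)
  treated <- rbinom(n, 1L, ps) == 1L
  treated[era_flag] <- TRUE
  ps[era_flag] <- 1
  data.frame(
    arm = factor(ifelse(treated, "treated", "control"),
                 levels = c("control", "treated")),
    true_ps = ps
  )
}

#' Simulate a relapse onset process
#'
#' Homogeneous Poisson relapse process over a follow-up window; the rate is
#' multiplied by the true incidence-rate ratio while treated and by an
#' optional gamma frailty (giving a negative-binomial marginal count).
#'
#' @param window_days Length of the observation window in days (> 0).
#' @param base_rate Control-arm relapse rate per year.
#' @param irr Treated-vs-control incidence rate ratio.
#' @param treated Logical; apply `irr` to the rate?
#' @param frailty Multiplicative patient frailty (mean 1).
#' @return Sorted numeric vector of relapse days in `(0, window_days]`.
#' @export
simulate_relapse_process <- function(window_days, base_rate, irr = 1,
                                     treated = FALSE, frailty = 1) {
  stopifnot(window_days > 0, base_rate >= 0, irr > 0, frailty >= 0)
  rate_day <- base_rate / 365.25 * frailty * irr^as.numeric(treated)
  if (rate_day <= 0) return(numeric())
  k <- rpois(1L, rate_day * window_days)
  if (k == 0L) return(numeric())
  sort(runif(k, 0, window_days))
}

#' Simulate treatment discontinuation under outcome-dependent censoring
#'
#' Draws a discontinuation time from a piecewise-exponential hazard
#' `hazard * exp(dependence * N(t))`, where `N(t)` counts relapses up to `t`.
#' `dependence = 0` gives plain exponential (non-informative) discontinuation;
#' positive values make patients with more on-treatment relapses stop earlier,
#' the "selection of treatment responders" mechanism that per-protocol
#' censoring is exposed to.
#'
#' @param relapse_days Numeric vector of relapse days (the outcome history).
#' @param hazard Baseline discontinuation hazard per year (>= 0).
#' @param dependence Increase in log-hazard per relapse.
#' @param min_day Day before which discontinuation cannot occur (the
#'   three-month minimum exposure of the study design).
#' @param horizon Administrative end of observation (days).
#' @return The discontinuation day, or `NA` if none occurs before `horizon`.
#' @export
simulate_discontinuation <- function(relapse_days = numeric(), hazard,
                                     dependence = 0, min_day = 0,
                                     horizon = Inf) {
  stopifnot(hazard >= 0)
  if (hazard == 0) return(NA_real_)
  h0 <- hazard / 365.25
  e <- rexp(1L)
  n0 <- sum(relapse_days <= min_day)
  breaks <- sort(relapse_days[relapse_days > min_day & relapse_days < horizon])
  lo <- c(min_day, breaks)
  hi <- c(breaks, horizon)
  nrel <- n0 + seq_along(lo) - 1L
  hseg <- h0 * exp(dependence * nrel)
  for (i in seq_along(lo)) {
    seg_h <- hseg[i] * (hi[i] - lo[i])
    if (e <= seg_h) return(lo[i] + e / hseg[i])
    e <- e - seg_h
  }
  NA_real_
}

#' Simulate an EDSS trajectory over scheduled visits
#'
#' Produces half-point-grid EDSS scores at the given visit days: the baseline
#' score, a sustained step up at a latent worsening day (step size equal to
#' the baseline-dependent worsening threshold) or a sustained step down at a
#' latent improvement day, and transient bumps at visits falling within
#' `bump_days` after a relapse onset — the feature that exercises the 30-day
#' relapse-exclusion rule of the confirmed-worsening detector. Latent event
#' days are drawn from exponential hazards scaled by the true hazard ratios
#' unless supplied; only the earlier of the two latent events manifests.
#'
#' @param baseline_edss Baseline EDSS on the half-point grid 0-10.
#' @param visit_days Sorted numeric vector of visit days (> 0).
#' @param relapse_days Relapse onset days used for transient bumps.
#' @param treated Logical; scales the latent hazards by the hazard ratios.
#' @param true_effects List with `hr_worsening` and `hr_improvement`.
#' @param worsening_rate,improvement_rate Latent event hazards per year for a
#'   control patient.
#' @param worsening_day,improvement_day Optional forced latent event days
#'   (`Inf` for never); when `NULL` they are drawn.
#' @param bump Transient EDSS elevation after a relapse (half-point multiple).
#' @param bump_days Duration of the transient elevation, days after onset.
#' @return `data.frame` with columns `day`, `edss`, plus attributes
#'   `worsening_day` and `improvement_day` (the latent days used).
#' @export
simulate_edss_trajectory <- function(baseline_edss, visit_days,
                                     relapse_days = numeric(),
                                     treated = FALSE,
                                     true_effects = list(hr_worsening = 1,
                                                         hr_improvement = 1),
                                     worsening_rate = 0.1,
                                     improvement_rate = 0.1,
                                     worsening_day = NULL,
                                     improvement_day = NULL,
                                     bump = 1.0, bump_days = 30) {
  if (!.on_edss_grid(baseline_edss))
    stop("baseline EDSS must be on the half-point grid 0-10", call. = FALSE)
  if (is.unsorted(visit_days)) visit_days <- sort(visit_days)
  draw_time <- function(rate_yr, hr) {
    r <- rate_yr / 365.25 * hr^as.numeric(treated)
    if (r <= 0) Inf else rexp(1L, r)
  }
  tw <- worsening_day %||% draw_time(worsening_rate, true_effects$hr_worsening)
  ti <- if (baseline_edss < 1.5) Inf
        else improvement_day %||% draw_time(improvement_rate,
                                            true_effects$hr_improvement)
  # competing latent events: only the first manifests
  if (tw <= ti) ti <- Inf else tw <- Inf
  s_w <- worsening_step(baseline_edss)
  s_i <- improvement_step(baseline_edss)
  if (is.na(s_i)) s_i <- 0
  bumped <- vapply(visit_days, function(d)
    any(d > relapse_days & d <= relapse_days + bump_days), logical(1))
  edss <- baseline_edss + s_w * (visit_days >= tw) - s_i * (visit_days >= ti) +
    bump * bumped
  edss <- pmin(10, pmax(0, edss))
  out <- data.frame(day = visit_days, edss = edss)
  attr(out, "worsening_day") <- tw
  attr(out, "improvement_day") <- ti
  out
}

# --- full registry generation ------------------------------------------------

# truncated normal / lognormal via inverse-CDF
.rtnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}
.rtlnorm <- function(n, meanlog, sdlog, lo, hi) {
  qlnorm(runif(n, plnorm(lo, meanlog, sdlog), plnorm(hi, meanlog, sdlog)),
         meanlog, sdlog)
}

.sample_edss <- function(band) {
  # half-point values within the Table-2 bands, skewed toward the low end
  low <- c(0, 1, 1.5); p_low <- c(0.25, 0.45, 0.30)
  mid <- c(2, 2.5, 3, 3.5); p_mid <- c(0.35, 0.30, 0.20, 0.15)
  high <- c(4, 4.5, 5, 5.5, 6, 6.5); p_high <- c(0.30, 0.25, 0.20, 0.15, 0.07, 0.03)
  out <- numeric(length(band))
  for (b in 1:3) {
    idx <- which(band == b)
    if (!length(idx)) next
    vals <- switch(b, low, mid, high)
    pr <- switch(b, p_low, p_mid, p_high)
    out[idx] <- vals[sample.int(length(vals), length(idx), TRUE, prob = pr)]
  }
  out
}

#' Generate a synthetic two-treatment registry with known ground truth
#'
#' Draws a complete four-table registry (patients, visits, relapses,
#' treatment episodes) from the data-generating law described in
#' [simulation_config()], together with the per-patient ground truth (true
#' propensity, latent event times, frailty, discontinuation day) needed to
#' validate every downstream estimator. Deterministic given the configuration
#' (including its seed); all dates are integer day offsets from the control
#' drug's availability date.
#'
#' By default every simulated patient satisfies the eligibility criteria of
#' the cohort module (a baseline EDSS visit on the index day, quarterly
#' post-baseline visits over at least two years, a minimum of three months on
#' the index drug), so the number of analysed patients equals `n_patients`
#' unless the era switch removes pre-availability patients in a restricted
#' analysis.
#'
#' @param config A [simulation_config()] object.
#' @return List of class `synthetic_registry` with elements `registry`
#'   (a `registry_tables` object) and `truth` (per-patient `data.table` with
#'   attribute `true_effects`).
#' @export
generate_registry <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  cp <- config$covariate_params
  op <- config$outcome_params
  te <- config$true_effects

  # --- countries and baseline covariates
  ci <- sample.int(nrow(config$countries), n, TRUE, prob = config$countries$prop)
  country <- config$countries$label[ci]
  source <- config$countries$source[ci]
  cint <- config$countries$intercept[ci]
  sex <- ifelse(runif(n) < cp$p_female, "F", "M")
  age <- .rtnorm(n, cp$age_mean, cp$age_sd, cp$age_range[1], cp$age_range[2])
  msd <- .rtlnorm(n, cp$msd_meanlog, cp$msd_sdlog, cp$msd_range[1], cp$msd_range[2])
  # pre-era patients (indexed before the control drug existed) are drawn from
  # a more active, more disabled subpopulation: confounded inclusion
  pre_era <- if (isTRUE(config$era$enabled))
    runif(n) < config$era$pre_era_fraction else rep(FALSE, n)
  edss_band <- sample.int(3L, n, TRUE, prob = cp$edss_band_probs)
  n_rel <- sample(0:(length(cp$relapse_probs) - 1L), n, TRUE,
                  prob = cp$relapse_probs)
  if (any(pre_era)) {
    np <- sum(pre_era)
    edss_band[pre_era] <- sample.int(3L, np, TRUE,
                                     prob = config$era$edss_band_probs)
    n_rel[pre_era] <- sample(0:(length(config$era$relapse_probs) - 1L), np,
                             TRUE, prob = config$era$relapse_probs)
  }
  b_edss <- .sample_edss(edss_band)
  n_tx <- sample(0:(length(cp$prior_tx_probs) - 1L), n, TRUE,
                 prob = cp$prior_tx_probs)
  act_w <- ifelse(n_rel >= 1,
                  runif(n) < cp$p_worsening_given_relapse,
                  runif(n) < cp$p_worsening_given_no_relapse)
  # a recorded pre-baseline confirmed worsening needs a reachable reference
  # score: lift baselines below 1.5 for those patients
  b_edss[act_w & b_edss < 1.5] <- 2.0
  activity <- ifelse(n_rel >= 1,
                     ifelse(act_w, "relapse and worsening", "relapse"),
                     ifelse(act_w, "worsening", "none"))

  # --- index dates and record horizon
  index <- sample(0:1800, n, TRUE)
  if (any(pre_era))
    index[pre_era] <- -sample(90:config$era$pre_era_span, sum(pre_era), TRUE)
  fu <- round(.rtlnorm(n, config$followup$meanlog, config$followup$sdlog,
                       config$followup$min_days, config$followup$max_days))

  # --- treatment assignment
  cov <- data.frame(sex = sex, age = age, ms_duration = msd,
                    baseline_edss = b_edss, n_relapses_prior_12m = n_rel,
                    n_prior_treatments = n_tx, prior_activity = activity)
  asg <- assign_treatment(cov, config$ps_coefficients, cint, pre_era)
  treated <- asg$arm == "treated"

  # --- relapse process with informative discontinuation
  frail <- if (op$frailty_var > 0)
    rgamma(n, shape = 1 / op$frailty_var, rate = 1 / op$frailty_var)
  else rep(1, n)
  log_rate <- log(op$base_relapse_rate / 365.25) +
    op$log_rate_per_prior_relapse * pmin(n_rel, 3) +
    op$log_rate_edss[edss_band]
  rate_day <- exp(log_rate) * frail
  rate_day[pre_era] <- rate_day[pre_era] * config$era$pre_era_rate_multiplier
  lam_on <- rate_day * ifelse(treated, te$irr_relapse, 1)
  lam_off <- if (isTRUE(op$effect_stops_at_discontinuation)) rate_day else lam_on
  h_disc <- ifelse(treated, config$discontinuation$rate_treated,
                   config$discontinuation$rate_control)

  # on-treatment relapse draws over the whole window, then discontinuation
  # given that history, then regeneration of the post-discontinuation tail
  # (exact by Poisson-process memorylessness)
  k_on <- rpois(n, lam_on * fu)
  rel_on <- rep(list(numeric()), n)
  pos <- which(k_on > 0)
  for (i in pos) rel_on[[i]] <- sort(runif(k_on[i], 0, fu[i]))
  disc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    disc[i] <- simulate_discontinuation(rel_on[[i]],
                                        hazard = h_disc[i],
                                        dependence = config$discontinuation$dependence,
                                        min_day = 91, horizon = fu[i])
  }
  relapses_rel <- rel_on
  redo <- which(!is.na(disc))
  for (i in redo) {
    keep <- relapses_rel[[i]][relapses_rel[[i]] <= disc[i]]
    tail_len <- fu[i] - disc[i]
    k2 <- if (lam_off[i] > 0 && tail_len > 0) rpois(1L, lam_off[i] * tail_len) else 0L
    tail_rel <- if (k2 > 0) sort(runif(k2, disc[i], fu[i])) else numeric()
    relapses_rel[[i]] <- c(keep, tail_rel)
  }

  # --- latent EDSS events (competing worsening/improvement)
  hw <- op$worsening_rate / 365.25 * ifelse(treated, te$hr_worsening, 1)
  hi_rate <- op$improvement_rate / 365.25 * ifelse(treated, te$hr_improvement, 1)
  t_w <- ifelse(hw > 0, rexp(n, pmax(hw, 1e-12)), Inf)
  t_i <- ifelse(b_edss >= 1.5 & hi_rate > 0, rexp(n, pmax(hi_rate, 1e-12)), Inf)
  drop_i <- t_w <= t_i
  t_i[drop_i] <- Inf
  t_w[!drop_i] <- Inf

  # --- visit schedule: pre-baseline history, index-day visit, follow-up
  vs <- config$visit_schedule
  pre_list <- .pre_index_visits(n, act_w, b_edss)
  nv <- pmax(1L, ceiling(fu / max(vs$mean_gap - 2 * vs$jitter, 20)) + 2L)
  vid <- rep(seq_len(n), nv)
  gaps <- pmax(14, round(rnorm(length(vid), vs$mean_gap, vs$jitter)))
  vdt <- data.table(patient_id = vid, gap = gaps)
  vdt[, day := cumsum(gap), by = patient_id]
  vdt <- vdt[day <= fu[patient_id]]

  # --- prior relapse dates (12-month window + occasional older onset)
  rel_prior <- .prior_relapse_offsets(n_rel, act_w, pre_list$conf_day)
  older <- which(runif(n) < 0.3)

  # --- assemble tables (absolute days)
  post_rel <- data.table(
    patient_id = rep(seq_len(n), lengths(relapses_rel)),
    date = unlist(lapply(seq_len(n), function(i)
      index[i] + ceiling(relapses_rel[[i]])), use.names = FALSE)
  )
  prior_rel <- data.table(
    patient_id = rep(seq_len(n), lengths(rel_prior)),
    date = unlist(lapply(seq_len(n), function(i)
      index[i] - rel_prior[[i]]), use.names = FALSE)
  )
  older_rel <- data.table(patient_id = older,
                          date = index[older] - sample(400:700, length(older), TRUE))
  relapses <- rbind(post_rel, prior_rel, older_rel)
  if (nrow(relapses)) relapses <- relapses[order(patient_id, date)]

  # post-index visit EDSS values
  vdt[, edss := {
    i <- patient_id
    base <- b_edss[i]
    val <- base +
      worsening_step(base) * (day >= t_w[i]) -
      ifelse(is.na(improvement_step(base)), 0, improvement_step(base)) *
        (day >= t_i[i])
    val
  }]
  # transient post-relapse bumps (post-index relapses only)
  if (nrow(post_rel) && op$relapse_bump > 0) {
    vdt[, row_id := .I]
    rel_rel <- data.table(
      patient_id = post_rel$patient_id,
      lo = post_rel$date - index[post_rel$patient_id],
      hi = post_rel$date - index[post_rel$patient_id] + op$bump_days
    )
    hits <- vdt[rel_rel, on = .(patient_id, day > lo, day <= hi),
                nomatch = NULL, x.row_id]
    if (length(hits)) vdt[unique(hits), edss := edss + op$relapse_bump]
    vdt[, row_id := NULL]
  }
  vdt[, edss := pmin(10, pmax(0, edss))]

  visits <- rbind(
    data.table(patient_id = pre_list$visits$patient_id,
               date = index[pre_list$visits$patient_id] - pre_list$visits$offset,
               edss = pre_list$visits$edss),
    data.table(patient_id = seq_len(n), date = index, edss = b_edss),
    data.table(patient_id = vdt$patient_id, date = index[vdt$patient_id] + vdt$day,
               edss = vdt$edss)
  )[order(patient_id, date)]

  treatments <- .build_treatments(n, index, disc, fu, n_tx, treated, pre_era)

  patients <- data.table(
    patient_id = seq_len(n),
    sex = sex,
    birth_year = 2011L + as.integer(floor(index / 365.25)) - round(age),
    onset_date = index - round(msd * 365.25),
    country = country,
    source = source
  )

  registry <- registry_tables(patients, visits, relapses, treatments,
                              meta = list(origin = "2011-01-01",
                                          availability_day = 0,
                                          seed = config$seed,
                                          n_patients = n))

  truth <- data.table(
    patient_id = seq_len(n),
    arm = asg$arm,
    true_ps = asg$true_ps,
    pre_era = pre_era,
    index_day = index,
    followup_days = fu,
    disc_day = ifelse(is.na(disc), NA_real_, ceiling(disc)),
    frailty = frail,
    control_rate_day = rate_day,
    t_worsening = t_w,
    t_improvement = t_i,
    baseline_edss = b_edss,
    n_relapses_prior_12m = n_rel,
    n_prior_treatments = n_tx,
    prior_activity = activity,
    age = age,
    ms_duration = msd
  )
  setattr(truth, "true_effects", te)

  structure(list(registry = registry, truth = truth),
            class = "synthetic_registry")
}

# pre-baseline EDSS visit history: patients flagged with prior confirmed
# worsening get a reference visit ~11-12 months back, the onset visit and a
# confirming visit >= 6 months later; flat patients get two stable visits
.pre_index_visits <- function(n, act_w, b_edss) {
  d_ref <- sample(330:364, n, TRUE)
  d_onset <- sample(250:280, n, TRUE)
  d_conf <- sample(30:60, n, TRUE)
  d_flat1 <- sample(280:340, n, TRUE)
  d_flat2 <- sample(30:90, n, TRUE)
  ref_edss <- ifelse(b_edss <= 1.5, 0, b_edss - 1)
  w <- which(act_w)
  f <- which(!act_w)
  visits <- rbind(
    data.table(patient_id = rep(w, 3L),
               offset = c(d_ref[w], d_onset[w], d_conf[w]),
               edss = c(ref_edss[w], b_edss[w], b_edss[w])),
    data.table(patient_id = rep(f, 2L),
               offset = c(d_flat1[f], d_flat2[f]),
               edss = c(b_edss[f], b_edss[f]))
  )
  list(visits = visits, conf_day = ifelse(act_w, d_conf, NA_real_))
}

# offsets (days before index) of the relapses inside the 12-month window;
# worsening patients must not have a relapse within the 30 days preceding
# their pre-baseline confirming visit, or the recorded activity category
# would not be recoverable
.prior_relapse_offsets <- function(n_rel, act_w, conf_day) {
  out <- vector("list", length(n_rel))
  idx <- which(n_rel > 0)
  for (i in idx) {
    k <- sample.int(365L, n_rel[i], replace = TRUE)
    if (act_w[i] && !is.na(conf_day[i])) {
      bad <- k > conf_day[i] & k <= conf_day[i] + 30
      k[bad] <- k[bad] + 31L
    }
    out[[i]] <- k
  }
  out
}

.nonstudy_drugs <- c("interferon beta", "glatiramer acetate",
                     "teriflunomide", "dimethyl fumarate")

.build_treatments <- function(n, index, disc, fu, n_tx, treated, pre_era) {
  # prior disease-modifying episodes stacked backwards from the index date
  total <- sum(n_tx)
  prior <- NULL
  if (total > 0) {
    pid <- rep(seq_len(n), n_tx)
    g <- sample(30:120, total, TRUE)
    d <- sample(180:900, total, TRUE)
    pdt <- data.table(patient_id = pid, gap = g, dur = d)
    pdt[, cum := cumsum(gap + dur), by = patient_id]
    prior <- data.table(
      patient_id = pdt$patient_id,
      drug = sample(.nonstudy_drugs, total, TRUE),
      start_date = index[pdt$patient_id] - pdt$cum,
      end_date = index[pdt$patient_id] - pdt$cum + pdt$dur
    )
  }
  end_idx <- ifelse(is.na(disc), NA_real_, index + ceiling(disc))
  study <- data.table(
    patient_id = seq_len(n),
    drug = ifelse(treated, "natalizumab", "fingolimod"),
    start_date = index,
    end_date = end_idx
  )
  # post-discontinuation switches (half of discontinuers start a new drug;
  # pre-era patients never switch onto a post-era study drug)
  sw_cand <- which(!is.na(disc))
  sw_cand <- sw_cand[runif(length(sw_cand)) < 0.5]
  switches <- NULL
  if (length(sw_cand)) {
    start2 <- index[sw_cand] + ceiling(disc[sw_cand]) +
      sample(14:90, length(sw_cand), TRUE)
    ok <- start2 < index[sw_cand] + fu[sw_cand] - 30
    sw_cand <- sw_cand[ok]; start2 <- start2[ok]
    if (length(sw_cand)) {
      other <- ifelse(treated[sw_cand], "fingolimod", "natalizumab")
      to_study <- runif(length(sw_cand)) < 0.4 & !pre_era[sw_cand]
      drug2 <- ifelse(to_study, other,
                      sample(.nonstudy_drugs, length(sw_cand), TRUE))
      switches <- data.table(patient_id = sw_cand, drug = drug2,
                             start_date = start2, end_date = NA_real_)
    }
  }
  out <- rbind(prior, study, switches)
  out[order(patient_id, start_date)]
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat("<synthetic_registry>\n")
  print(x$registry)
  tab <- table(x$truth$arm)
  cat(sprintf("  arms: %d treated / %d control", tab[["treated"]],
              tab[["control"]]))
  if (any(x$truth$pre_era))
    cat(sprintf(" (%d pre-era)", sum(x$truth$pre_era)))
  cat("\n")
  invisible(x)
}
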