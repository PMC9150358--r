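# Propensity-score estimation and overlap diagnostics.
#
# The score is the probability of starting the treated drug conditional on
# sex, age, MS duration, baseline EDSS band, prior-relapse band,
# prior-treatment band and prior clinical activity, with country as a random
# intercept (mixed-effects logistic). Age and MS duration enter linearly;
# the remaining covariates use the bands the study tabulates.

# covariate coding shared by the PS model and the balance table
.ps_code <- function(baseline) {
  dt <- as.data.table(baseline)
  data.table(
    patient_id = dt$patient_id,
    treated = as.integer(dt$arm == "treated"),
    arm = dt$arm,
    sex = factor(dt$sex, levels = c("F", "M")),
    age = dt$age,
    ms_duration = dt$ms_duration,
    edss_band = cut(dt$baseline_edss, c(-Inf, 2, 4, Inf),
                    labels = c("<2", "2-3.5", "4+"), right = FALSE),
    rel_band = factor(pmin(dt$n_relapses_prior_12m, 3),
                      levels = 0:3, labels = c("0", "1", "2", "3+")),
    tx_band = factor(pmin(dt$n_prior_treatments, 3),
                     levels = 0:3, labels = c("0", "1", "2", "3+")),
    activity = factor(dt$prior_activity,
                      levels = c("none", "worsening", "relapse",
                                 "relapse and worsening")),
    # the relapse component of the activity category is determined by the
    # relapse-count band (relapse categories iff count >= 1), so only the
    # worsening component enters the model; the 4-level factor would be
    # rank-deficient alongside rel_band
    act_w_only = as.integer(dt$prior_activity == "worsening"),
    act_both = as.integer(dt$prior_activity == "relapse and worsening"),
    country = factor(dt$country)
  )
}

.ps_covariates <- c("sex", "age", "ms_duration", "edss_band", "rel_band",
                    "tx_band", "act_w_only", "act_both")

#' Fit the propensity-score model
#'
#' Mixed-effects logistic regression of treatment on the baseline covariates
#' with a country random intercept. If the mixed model fails to converge (or
#' the data hold a single country) the model falls back to fixed country
#' indicators — recorded in the returned object — since the scientific
#' target is the score, not the variance component. Complete separation (a
#' covariate level observed in one arm only) is rejected with an error
#' naming the level.
#'
#' @param baseline Baseline table from [apply_eligibility()].
#' @param use_random_country Use a random country intercept (otherwise fixed
#'   indicators).
#' @return Object of class `ps_model` with elements `fit`, `type`
#'   (`"glmm"`/`"glm"`), `fallback` (logical), `coefficients`,
#'   `country_effects` and the covariate coding levels.
#' @export
fit_ps_model <- function(baseline, use_random_country = TRUE) {
  dat <- .ps_code(baseline)
  if (min(table(dat$arm)) < 2)
    stop("need at least 2 patients per arm to fit the PS model",
         call. = FALSE)
  for (v in c("sex", "edss_band", "rel_band", "tx_band", "activity")) {
    tab <- table(dat[[v]], dat$arm)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    sep <- rownames(tab)[apply(tab, 1, function(r) any(r == 0))]
    if (length(sep))
      stop(sprintf("separation: level '%s' of '%s' occurs in one arm only",
                   sep[1], v), call. = FALSE)
  }
  if (anyNA(dat))
    stop("missing covariate values in the baseline table", call. = FALSE)
  # degenerate (constant) covariates carry no assignment information and
  # would make the design rank-deficient
  active <- .ps_covariates[vapply(.ps_covariates, function(v) {
    x <- dat[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1 else var(x) > 1e-12
  }, logical(1))]
  if (!length(active))
    stop("all PS covariates are constant", call. = FALSE)
  fe <- paste(active, collapse = " + ")
  fallback <- FALSE
  fit <- NULL
  type <- "glm"
  if (use_random_country && nlevels(droplevels(dat$country)) > 1) {
    fml <- as.formula(paste("treated ~", fe, "+ (1 | country)"))
    fit <- tryCatch({
      f <- lme4::glmer(fml, data = dat, family = binomial(),
                       control = lme4::glmerControl(calc.derivs = FALSE))
      if (length(f@optinfo$conv$lme4$messages %||% character())) NULL else f
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) type <- "glmm" else fallback <- use_random_country
  } else if (use_random_country) {
    fallback <- TRUE
  }
  if (is.null(fit)) {
    fe_full <- if (nlevels(droplevels(dat$country)) > 1)
      paste(fe, "+ country") else fe
    fit <- glm(as.formula(paste("treated ~", fe_full)), data = dat,
               family = binomial())
  }
  co <- if (type == "glmm") lme4::fixef(fit) else coef(fit)
  if (any(!is.finite(co)))
    stop("PS model produced non-finite coefficients", call. = FALSE)
  ce <- if (type == "glmm") {
    re <- lme4::ranef(fit)$country
    setNames(re[["(Intercept)"]], rownames(re))
  } else {
    cn <- grep("^country", names(co), value = TRUE)
    setNames(co[cn], sub("^country", "", cn))
  }
  structure(list(fit = fit, type = type, fallback = fallback,
                 coefficients = co, country_effects = ce,
                 country_levels = levels(droplevels(dat$country)),
                 n = nrow(dat)),
            class = "ps_model")
}

#' Predict propensity scores
#'
#' Applies a fitted [fit_ps_model()] to a baseline table. Country levels
#' unseen at fit time are rejected rather than silently extrapolated.
#' Scores are clipped to `[1e-6, 1 - 1e-6]` so that numeric underflow cannot
#' manufacture infinite weights, while genuine positivity violations stay
#' visible in the overlap diagnostics.
#'
#' @param model A `ps_model`.
#' @param baseline Baseline table using the model's covariate coding.
#' @return `data.table` of class `ps_result`: `patient_id`, `arm`, `ps`,
#'   `lp` (linear predictor).
#' @export
predict_ps <- function(model, baseline) {
  stopifnot(inherits(model, "ps_model"))
  dat <- .ps_code(baseline)
  newc <- setdiff(unique(as.character(dat$country)), model$country_levels)
  if (length(newc))
    stop("unseen country level(s): ", paste(newc, collapse = ", "),
         call. = FALSE)
  dat[, country := factor(as.character(country),
                          levels = model$country_levels)]
  lp <- if (model$type == "glmm")
    predict(model$fit, newdata = dat, type = "link")
  else
    predict(model$fit, newdata = dat, type = "link")
  ps <- pmin(1 - 1e-6, pmax(1e-6, plogis(lp)))
  out <- data.table(patient_id = dat$patient_id, arm = dat$arm,
                    ps = as.numeric(ps), lp = as.numeric(lp))
  setattr(out, "class", c("ps_result", class(out)))
  out[]
}

#' Assess propensity-score overlap and common support
#'
#' Summarizes the per-arm score distributions, the common-support interval
#' (maximum of arm minima to minimum of arm maxima), the fraction of each
#' arm falling outside it, and the two-sample Kolmogorov-Smirnov statistic —
#' the diagnostics used to judge the positivity assumption.
#'
#' @param ps A `ps_result` from [predict_ps()].
#' @return List of class `overlap_report`.
#' @export
assess_overlap <- function(ps) {
  stopifnot(all(c("arm", "ps") %in% names(ps)))
  p_t <- ps$ps[ps$arm == "treated"]
  p_c <- ps$ps[ps$arm == "control"]
  if (!length(p_t) || !length(p_c))
    stop("both arms must be present", call. = FALSE)
  support <- c(lo = max(min(p_t), min(p_c)), hi = min(max(p_t), max(p_c)))
  summ <- function(p) c(n = length(p), min = min(p),
                        q1 = unname(quantile(p, 0.25)), median = median(p),
                        q3 = unname(quantile(p, 0.75)), max = max(p),
                        mean = mean(p))
  ks <- suppressWarnings(unname(ks.test(p_t, p_c)$statistic))
  structure(list(
    treated = summ(p_t), control = summ(p_c), support = support,
    frac_outside = c(
      treated = mean(p_t < support["lo"] | p_t > support["hi"]),
      control = mean(p_c < support["lo"] | p_c > support["hi"])),
    ks = ks), class = "overlap_report")
}

#' @export
print.ps_model <- function(x, ...) {
  cat("<ps_model>", x$type,
      if (x$fallback) "(fixed-country fallback)" else "", "\n")
  cat("  n =", x$n, "; covariates:", paste(.ps_covariates, collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  cat(sprintf("  common support: [%.3f, %.3f]  KS = %.3f\n",
              x$support["lo"], x$support["hi"], x$ks))
  cat(sprintf("  outside support: treated %.1f%%, control %.1f%%\n",
              100 * x$frac_outside["treated"],
              100 * x$frac_outside["control"]))
  invisible(x)
}
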