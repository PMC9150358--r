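# Outcome models: negative-binomial incidence-rate ratios with a follow-up
# offset, and Cox proportional-hazards ratios, with variance estimation
# matched to the design — robust sandwich under weighting, pair-clustered
# estimating equations or a gamma frailty term under matching.

.new_estimate <- function(measure, b, se, n_used, variance_method,
                          design_info, note = NULL) {
  structure(list(
    measure = measure,
    point = exp(b),
    ci = c(lo = exp(b - 1.96 * se), hi = exp(b + 1.96 * se)),
    se_log = se,
    n_used = n_used,
    variance_method = variance_method,
    design = design_info,
    note = note), class = "estimate_result")
}

# resolve a design object into data + weights/pairs + provenance
.design_data <- function(records, design) {
  dat <- as.data.table(records)
  dat[, arm := factor(arm, levels = c("control", "treated"))]
  if (is.null(design)) {
    list(dat = dat, weights = NULL, pair = NULL,
         info = list(type = "none", estimand = "unadjusted"))
  } else if (inherits(design, "weighted_cohort")) {
    wd <- merge(dat, design[, .(patient_id, weight)], by = "patient_id")
    list(dat = wd, weights = wd$weight, pair = NULL,
         info = list(type = "weighted", scheme = attr(design, "scheme"),
                     estimand = attr(design, "estimand")))
  } else if (inherits(design, "matched_cohort")) {
    long <- rbind(design$pairs[, .(pair_id, patient_id = treated_id)],
                  design$pairs[, .(pair_id, patient_id = control_id)])
    md <- merge(dat, long, by = "patient_id")
    list(dat = md, weights = NULL, pair = md$pair_id,
         info = list(type = "matched", caliper = design$caliper_sd,
                     estimand = "ATT"))
  } else {
    stop("design must be NULL, a weighted_cohort or a matched_cohort",
         call. = FALSE)
  }
}

#' Negative-binomial incidence-rate ratio for relapse counts
#'
#' Regression of the relapse count on treatment arm with a log follow-up
#' offset. Weighted designs use the weights in the likelihood with a robust
#' sandwich variance; matched designs use pair-clustered estimating
#' equations (independence working correlation). If the dispersion collapses
#' towards zero (or the NB fit fails) the model falls back to Poisson with
#' robust variance, recorded in the result.
#'
#' @param records Outcome records with `patient_id`, `arm`, `count`,
#'   `exposure_days` (> 0).
#' @param design `NULL`, a `weighted_cohort`, or a `matched_cohort`.
#' @return An `estimate_result` with `measure = "IRR"` (treated vs control).
#' @export
fit_nb_irr <- function(records, design = NULL) {
  dd <- .design_data(records, design)
  dat <- dd$dat
  if (any(dat$exposure_days <= 0))
    stop("all records need positive exposure", call. = FALSE)
  for (a in levels(dat$arm)) {
    if (sum(dat$count[dat$arm == a]) == 0)
      stop(sprintf(
        "all relapse counts are zero in the %s arm; the rate ratio is not identified by NB regression (consider exact conditional methods)",
        a), call. = FALSE)
  }
  dat[, off := log(exposure_days / 365.25)]
  dat[, w_ := if (is.null(dd$weights)) 1 else dd$weights]
  note <- NULL
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(count ~ arm + offset(off), data = dat,
                                  weights = w_)),
    error = function(e) NULL)
  if (!is.null(fit) && is.null(fit$th.warn) && fit$theta > 1e4) fit <- NULL
  if (is.null(fit) || !fit$converged || fit$theta > 1e4) {
    fit <- glm(count ~ arm + offset(off), data = dat, family = poisson(),
               weights = w_)
    note <- "NB dispersion degenerate or fit failed; Poisson with robust variance"
  }
  b <- coef(fit)[["armtreated"]]
  if (dd$info$type == "matched") {
    V <- sandwich::vcovCL(fit, cluster = dd$pair)
    vm <- "cluster-by-pair"
  } else if (dd$info$type == "weighted" || !is.null(note)) {
    V <- sandwich::vcovHC(fit, type = "HC0")
    vm <- "robust sandwich"
  } else {
    V <- vcov(fit)
    vm <- "model-based"
  }
  se <- sqrt(V["armtreated", "armtreated"])
  .new_estimate("IRR", b, se, nrow(dat), vm, dd$info, note)
}

#' Cox proportional-hazards ratio for time-to-event outcomes
#'
#' Proportional-hazards regression of the (follow-up, event) pair on
#' treatment arm, optionally adjusted for annualized visit density (linear
#' on the log-hazard scale) — mandatory for the disability outcomes, whose
#' detection probability depends on how often EDSS is scored. Weighted
#' designs use a weighted partial likelihood with robust variance; matched
#' designs use a gamma frailty term per pair, with a documented fallback to
#' pair-clustered robust variance if the frailty fit fails. Ties use the
#' Efron approximation.
#'
#' @param records Outcome records with `patient_id`, `arm`, `time` (> 0),
#'   `event`, and `visit_density` when adjusting.
#' @param design `NULL`, a `weighted_cohort`, or a `matched_cohort`.
#' @param adjust_visit_density Add the visit-density covariate.
#' @return An `estimate_result` with `measure = "HR"` (treated vs control).
#' @export
fit_cox_hr <- function(records, design = NULL, adjust_visit_density = FALSE) {
  dd <- .design_data(records, design)
  dat <- dd$dat
  dat <- dat[time > 0]
  if (sum(dat$event) == 0)
    stop("no events observed; hazard ratio not estimable", call. = FALSE)
  rhs <- "arm"
  if (adjust_visit_density) {
    stopifnot("visit_density" %in% names(dat))
    rhs <- paste(rhs, "+ visit_density")
  }
  note <- NULL
  if (dd$info$type == "matched") {
    dat[, pair_ := dd$pair[match(dat$patient_id, dd$dat$patient_id)]]
    fml_fr <- as.formula(paste("Surv(time, event) ~", rhs,
                               "+ frailty(pair_, distribution = 'gamma')"))
    fit <- tryCatch(suppressWarnings(
      coxph(fml_fr, data = dat, ties = "efron")),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sf <- summary(fit)$coefficients
      b <- sf["armtreated", "coef"]
      se <- sf["armtreated", "se(coef)"]
      vm <- "frailty"
    } else {
      fml_cl <- as.formula(paste("Surv(time, event) ~", rhs,
                                 "+ cluster(pair_)"))
      fit <- coxph(fml_cl, data = dat, ties = "efron", robust = TRUE)
      b <- coef(fit)[["armtreated"]]
      se <- sqrt(vcov(fit)["armtreated", "armtreated"])
      vm <- "cluster-by-pair"
      note <- "frailty fit failed; pair-clustered robust variance"
    }
  } else if (dd$info$type == "weighted") {
    fml <- as.formula(paste("Surv(time, event) ~", rhs))
    dat[, w_ := dd$weights[match(dat$patient_id, dd$dat$patient_id)]]
    fit <- coxph(fml, data = dat, weights = w_, robust = TRUE,
                 ties = "efron")
    b <- coef(fit)[["armtreated"]]
    se <- sqrt(vcov(fit)["armtreated", "armtreated"])
    vm <- "robust sandwich"
  } else {
    fml <- as.formula(paste("Surv(time, event) ~", rhs))
    fit <- coxph(fml, data = dat, ties = "efron")
    b <- coef(fit)[["armtreated"]]
    se <- sqrt(vcov(fit)["armtreated", "armtreated"])
    vm <- "model-based"
  }
  .new_estimate("HR", b, se, nrow(dat), vm, dd$info, note)
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("<estimate_result> %s = %.3f [%.3f, %.3f]  (n = %d, %s, %s)\n",
              x$measure, x$point, x$ci["lo"], x$ci["hi"], x$n_used,
              x$design$type, x$variance_method))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
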