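# Matched and weighted designs (ATT / ATE) and covariate-balance metrics.

#' One-to-one greedy nearest-neighbor caliper matching
#'
#' Treated patients are processed in a seeded uniform-random order; each
#' takes the nearest unused control by propensity-score distance (ties broken
#' uniformly at random), without replacement, provided the distance does not
#' exceed the caliper. The caliper is expressed as a multiple of the
#' standard deviation of the score over the pooled sample, on the
#' probability scale.
#'
#' @param ps A `ps_result` from [predict_ps()].
#' @param caliper_sd Caliper as a multiple of the pooled PS standard
#'   deviation (> 0); the study used 0.02, 0.1 and 0.2.
#' @param seed Integer seed for the processing order and tie-breaks.
#' @param order Optional explicit processing order (a permutation of the
#'   treated patients' row indices); when supplied, randomness is used only
#'   for tie-breaks. Mainly for cross-checking against reference
#'   implementations.
#' @return Object of class `matched_cohort`: `pairs` (`pair_id`,
#'   `treated_id`, `control_id`, `distance`), `caliper_sd`,
#'   `caliper_absolute`, `seed`, `unmatched_treated`.
#' @export
match_greedy <- function(ps, caliper_sd = 0.2, seed = 1L, order = NULL) {
  stopifnot(caliper_sd > 0)
  p_t <- ps$ps[ps$arm == "treated"]; id_t <- ps$patient_id[ps$arm == "treated"]
  p_c <- ps$ps[ps$arm == "control"]; id_c <- ps$patient_id[ps$arm == "control"]
  if (!length(p_t))
    stop("no treated patients to match", call. = FALSE)
  cal <- caliper_sd * sd(ps$ps)
  if (!length(p_c)) {
    warning("empty control pool; returning an empty matched cohort",
            call. = FALSE)
    return(structure(list(pairs = data.table(pair_id = integer(),
                                             treated_id = integer(),
                                             control_id = integer(),
                                             distance = numeric()),
                          caliper_sd = caliper_sd, caliper_absolute = cal,
                          seed = seed, unmatched_treated = id_t),
                     class = "matched_cohort"))
  }
  res <- withr::with_seed(seed, {
    ord <- if (is.null(order)) sample.int(length(p_t)) else order
    used <- rep(FALSE, length(p_c))
    tr <- integer(); co <- integer(); di <- numeric()
    for (i in ord) {
      d <- abs(p_c - p_t[i])
      d[used] <- Inf
      dmin <- min(d)
      if (dmin <= cal + 1e-12) {
        cand <- which(d <= dmin + 1e-12)
        pick <- cand[sample.int(length(cand), 1L)]
        used[pick] <- TRUE
        tr <- c(tr, i); co <- c(co, pick); di <- c(di, dmin)
      }
    }
    list(tr = tr, co = co, di = di)
  })
  pairs <- data.table(pair_id = seq_along(res$tr),
                      treated_id = id_t[res$tr],
                      control_id = id_c[res$co],
                      distance = res$di)
  structure(list(pairs = pairs, caliper_sd = caliper_sd,
                 caliper_absolute = cal, seed = seed,
                 unmatched_treated = setdiff(id_t, pairs$treated_id)),
            class = "matched_cohort")
}

#' Propensity-score weights (IPTW, stabilized IPTW, odds)
#'
#' `iptw`: treated weight `1/p`, control `1/(1-p)` (ATE). `siptw`: the IPTW
#' weights multiplied by the marginal probability of the treatment actually
#' received, taming extreme weights (ATE). `odds`: treated weight 1, control
#' `p/(1-p)`, reweighting controls to the treated covariate distribution
#' (ATT).
#'
#' @param ps A `ps_result`.
#' @param scheme `"iptw"`, `"siptw"` or `"odds"`.
#' @return `data.table` of class `weighted_cohort` (`patient_id`, `arm`,
#'   `ps`, `weight`) with attributes `scheme`, `estimand` and
#'   `marginal_treated`.
#' @export
compute_weights <- function(ps, scheme = c("siptw", "iptw", "odds")) {
  scheme <- match.arg(scheme)
  p <- ps$ps
  if (any(p <= 0 | p >= 1))
    stop("propensity scores at 0 or 1: positivity violated, weights undefined",
         call. = FALSE)
  treated <- ps$arm == "treated"
  marg <- mean(treated)
  w <- switch(scheme,
    iptw = ifelse(treated, 1 / p, 1 / (1 - p)),
    siptw = ifelse(treated, marg / p, (1 - marg) / (1 - p)),
    odds = ifelse(treated, 1, p / (1 - p))
  )
  out <- data.table(patient_id = ps$patient_id, arm = ps$arm, ps = p,
                    weight = w)
  setattr(out, "class", c("weighted_cohort", class(out)))
  setattr(out, "scheme", scheme)
  setattr(out, "estimand", if (scheme == "odds") "ATT" else "ATE")
  setattr(out, "marginal_treated", marg)
  out[]
}

# weighted mean / variance (population-style normalization)
.wmean <- function(x, w) sum(w * x) / sum(w)
.wvar <- function(x, w) {
  m <- .wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

.smd <- function(x, w, treated) {
  mt <- .wmean(x[treated], w[treated]); mc <- .wmean(x[!treated], w[!treated])
  vt <- .wvar(x[treated], w[treated]); vc <- .wvar(x[!treated], w[!treated])
  pool <- (vt + vc) / 2
  if (pool <= 0) {
    if (abs(mt - mc) < 1e-12) return(0)
    return(Inf)
  }
  abs(mt - mc) / sqrt(pool)
}

# Mahalanobis distance of the K-1 weighted proportion vectors, pooled
# multinomial indicator covariance with a small ridge for invertibility
.mahalanobis_cat <- function(f, w, treated) {
  lev <- levels(f)
  if (length(lev) < 2) return(0)
  lev <- lev[-1L]
  props <- function(sel) {
    vapply(lev, function(l) .wmean(f[sel] == l, w[sel]), numeric(1))
  }
  p_t <- props(treated); p_c <- props(!treated)
  covm <- function(p) diag(p, length(p)) - tcrossprod(p)
  S <- (covm(p_t) + covm(p_c)) / 2 + diag(1e-10, length(lev))
  d <- p_t - p_c
  sqrt(drop(t(d) %*% solve(S, d)))
}

#' Covariate balance before and after a matched or weighted design
#'
#' Standardized mean differences for continuous and binary covariates,
#' Mahalanobis distances of the category-proportion vectors for
#' multi-category covariates, before and after applying the design; 10% is
#' the conventional acceptability threshold. Matched designs use the matched
#' patients with unit weights.
#'
#' @param baseline Baseline table.
#' @param design A `matched_cohort`, a `weighted_cohort`, or `NULL` (no
#'   design: after equals before).
#' @return `data.table` of class `balance_report`: `covariate`, `metric`,
#'   `before`, `after`, `flag` (TRUE when after-balance exceeds 0.10).
#' @export
balance_table <- function(baseline, design = NULL) {
  dat <- .ps_code(baseline)
  specs <- list(
    sex = "binary", age = "continuous", ms_duration = "continuous",
    edss_band = "categorical", rel_band = "categorical",
    tx_band = "categorical", activity = "categorical",
    country = "categorical"
  )
  one_pass <- function(d, w) {
    treated <- d$arm == "treated"
    vapply(names(specs), function(v) {
      if (specs[[v]] == "continuous") .smd(d[[v]], w, treated)
      else if (specs[[v]] == "binary") .smd(as.numeric(d[[v]] == levels(d[[v]])[2]),
                                            w, treated)
      else .mahalanobis_cat(droplevels(d[[v]]), w, treated)
    }, numeric(1))
  }
  before <- one_pass(dat, rep(1, nrow(dat)))
  if (is.null(design)) {
    after <- before
  } else if (inherits(design, "matched_cohort")) {
    keep <- c(design$pairs$treated_id, design$pairs$control_id)
    sub <- dat[patient_id %in% keep]
    after <- one_pass(sub, rep(1, nrow(sub)))
  } else if (inherits(design, "weighted_cohort")) {
    wd <- merge(dat, design[, .(patient_id, weight)], by = "patient_id")
    after <- one_pass(wd, wd$weight)
  } else {
    stop("design must be a matched_cohort, weighted_cohort or NULL",
         call. = FALSE)
  }
  out <- data.table(
    covariate = names(specs),
    metric = ifelse(unlist(specs) == "categorical", "mahalanobis", "smd"),
    before = unname(before), after = unname(after)
  )
  out[, flag := !is.finite(after) | after > 0.10]
  setattr(out, "class", c("balance_report", class(out)))
  out[]
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d pairs | caliper %.2f SD (%.4f) | %d unmatched treated\n",
              nrow(x$pairs), x$caliper_sd, x$caliper_absolute,
              length(x$unmatched_treated)))
  invisible(x)
}
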