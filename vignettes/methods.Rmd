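---
title: "Design grids for two-treatment registry comparisons: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design grids for two-treatment registry comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`psgrid` implements a comparative-effectiveness analysis pipeline for
two-treatment longitudinal registry data — the setting of natalizumab versus
fingolimod in relapsing–remitting multiple sclerosis — together with a
synthetic registry generator whose data-generating law mirrors, and therefore
makes testable, every assumption the analysis relies on. This vignette is the
package's account of the science: the models, the tunable parameters, the
numerical conventions, and what the validation does and does not establish.

## 1. The analysis pipeline

### Cohort and baseline

The index episode is the earliest study-drug episode starting on or after the
control drug's availability date and continued for at least three months
(90 days); open-ended episodes qualify when observed at least 90 days. Prior
exposure to therapies with extended duration of effect (mitoxantrone,
alemtuzumab, cladribine, daclizumab, rituximab, ocrelizumab) or off-label
cyclophosphamide disqualifies a patient. Eligibility requires a baseline EDSS
within the six months up to and including the index day (the most recent one
is the baseline), two post-baseline EDSS visits at least six months apart,
and at least one on-treatment visit. Month-denominated windows are fixed in
days (183 / 365 / 90) so results are reproducible at day resolution; the
index-day visit counts both as baseline and as on-treatment — the natural
reading of an EDSS scored at treatment start, though conventions differ.

Baseline covariates are sex, age, MS duration, baseline EDSS, counts of
prior treatments and of relapses in the previous 12 months, and the nature
of prior clinical activity (none / worsening only / relapse only / both).
The worsening component of prior activity has no standard operational
definition; we reuse the confirmed-change detector (Section "Outcomes")
anchored on the earliest EDSS in the 12-month lookback as reference. This is
a stand-in convention, flagged as such.

### Propensity score

Mixed-effects logistic regression of treatment on the covariates above with
a country random intercept. Age and MS duration enter linearly; EDSS,
prior-relapse and prior-treatment counts enter as the bands used in the
field's descriptive tables (EDSS <2 / 2–3.5 / ≥4; counts 0 / 1 / 2 / 3+);
the source tables imply this coding but do not state it, so it is a
documented inference. Prior activity enters as its two worsening indicators
(worsening-only, relapse-and-worsening): the relapse component of the
4-level category is logically determined by the relapse-count band
(relapse categories occur exactly when the count is ≥ 1), so the full
factor would be rank-deficient alongside it. When the mixed model fails to
converge — or a single country is present — the model falls back to fixed
country indicators and records that it did; the scientific target is the
score, not the variance component. Complete separation is an error naming
the offending level rather than a silent infinite coefficient. Fitted
scores are clipped to `[1e-6, 1 - 1e-6]`: numeric underflow must not
manufacture infinite weights, while genuine positivity violations remain
visible in the overlap report (per-arm distributions, common-support
interval, fractions outside it, between-arm Kolmogorov–Smirnov statistic).

### Designs: matching and weighting

One-to-one greedy nearest-neighbour matching processes treated patients in a
seeded uniform-random order; each takes the nearest unused control within
the caliper, ties broken uniformly at random, without replacement. The
caliper is a multiple (0.02, 0.1, 0.2) of the pooled standard deviation of
the score, on the probability scale — the source describes "standard
deviations of the PS", not of its logit. Matching (and odds weighting)
targets the ATT; IPTW and stabilized IPTW target the ATE. Stabilization
multiplies each weight by the marginal probability of the treatment actually
received; no trimming or truncation is applied, stabilization being the
chosen alternative. Balance is quantified by standardized mean differences
(weighted means and population-style weighted variances) and, for
multi-level categories, the Mahalanobis distance of the K−1 weighted
proportion vectors under the pooled multinomial indicator covariance with a
`1e-10` ridge for invertibility; 10% is the acceptability threshold.
Matching is unstratified: country enters only the propensity model, since
nothing indicates the original analyses matched within registry.

### Outcomes

Four outcomes: relapse count (with exposure), time to first relapse, time to
first confirmed EDSS worsening, time to first confirmed improvement.
Relapse onsets are counted in the half-open window `(start, end]` — an
onset on the index day belongs to baseline history; events exactly at the
window end are included (closed right endpoint) for deterministic boundary
behaviour.

The confirmed-change detector scans in-window visits in order. A candidate
onset is the first visit whose change from the fixed baseline meets the
threshold (worsening: +1.5 steps from EDSS 0, +1.0 up to 5.5, +0.5 above;
improvement: −1.5 from 1.5, −1.0 for 2.0–6.0, −0.5 above 6.0, undefined
below 1.5). Confirmation needs a visit at least 180 days later with every
intervening visit (inclusive) at threshold; a worsening confirmation cannot
fall within the 30 days after a relapse onset — improvement has no relapse
clause. A candidate failed by a sub-threshold visit is discarded and
scanning resumes after the failing visit, so later genuine events are still
found. Events are timed at the onset visit, the registry convention,
although timing at confirmation would also be defensible. The threshold
band for a reference EDSS of 0.5 is undefined in the standard definition
(bands 0 / 1.0–5.5 / >5.5); we close the gap by treating (0, 5.5] as the
middle band. Disability models adjust for annualized visit density (EDSS
visits per follow-up year, linear on the log-hazard scale) because
detection probability rises with visit frequency. Follow-up is summarized
by the reverse Kaplan–Meier estimator (censoring as the "event", log-log
confidence limits).

### Contrasts

Intention-to-treat runs from index to last record regardless of treatment
changes; per-protocol ends at the index-episode discontinuation or the last
record, whichever is earlier; pairwise censoring truncates both members of
a matched pair to the shorter follow-up and is applied after the base
windows are formed, so either combination is runnable. Per-protocol windows
are provably contained in ITT windows, and pairwise censoring is idempotent
— both are enforced by tests.

### Estimation

Relapse counts: negative-binomial regression on arm with a log
person-years offset, dispersion by maximum likelihood. Weighted designs put
the weights in the estimating equations and use HC0 robust sandwich
variance; matched designs use pair-clustered sandwich variance, which is
exactly a generalized estimating equation with independence working
correlation (a dedicated GEE engine is not required). If the dispersion
degenerates the model falls back to Poisson with robust variance and says
so in the result. Time-to-event outcomes: Cox proportional hazards with
Efron ties; weighted partial likelihood with robust variance under
weighting; a gamma frailty term per pair under matching, with a documented
fallback to pair-clustered robust variance if the frailty fit fails.
Confidence intervals are Wald on the log scale. Weighted-and-matched
combinations do not exist in the design grid and are rejected.

### The grid and the positivity sensitivity

The default grid is the full crossing per outcome: three calipers × two
contrasts × pairwise on/off (12 matched cells) plus two weighting schemes ×
two contrasts (4 weighted cells) — 64 cells over the four outcomes, the
literal crossing of the study's design table, subsettable by configuration.
One master seed expands into fixed per-caliper matching seeds, so reruns are
identical and cells are order-invariant; per-cell failures are recorded
without stopping the run. The positivity sensitivity runs the same grid
restricted (index episodes after availability only) and unrestricted
(pre-era patients included), reporting per-cell estimate shifts, the
between-arm KS of each run and per-arm KS shifts of the score
distributions between runs.

## 2. The synthetic registry generator

The generator inverts the analysis assumptions as a data-generating law.
All dates are integer day offsets from the availability date (day 0);
calendar formatting happens only at I/O.

* **Assignment** is logistic on exactly the analysis covariate set plus a
  country intercept, with coefficients oriented as confounding by
  indication: more active and more disabled patients preferentially receive
  the treated drug, while treatment-naive patients do as well. The default
  intercept puts the marginal treated fraction near 0.39, the treated share
  of the motivating study (inverse-logit of −0.447). The activity-relapse
  coefficient is aliased with the relapse-count bands and defaults to zero
  so the generating model is identifiable under the analysis coding.
* **Relapses** are Poisson with a per-patient rate: 0.40/year at reference,
  multiplied by modest covariate effects (log-rate +0.15 per prior-relapse
  band, +0.05/+0.10 per EDSS band), a gamma frailty, and the true incidence
  rate ratio while on the treated drug. Marginally the counts are negative
  binomial. The frailty variance defaults to 0.15: strong frailty would
  make the marginal time-to-first-relapse hazard ratio visibly larger than
  the conditional generating ratio (hazard ratios do not collapse), so the
  configured "true" effects would no longer be the quantity any of the
  grid's analyses estimates; at 0.15 the gap stays around 2% while counts
  remain genuinely overdispersed. For the same reason the first-relapse
  hazard ratio is the relapse IRR — one Poisson process generates both —
  and `hr_relapse` is documented as implied rather than independently
  settable.
* **Discontinuation** is exponential from day 91 (the three-month eligibility
  minimum) at 0.30/year per arm — matching on-treatment medians near two
  years — with log-hazard increasing by 0.3 per on-treatment relapse:
  informative censoring, the "treatment responder selection" that
  per-protocol analyses are exposed to. The rates are symmetric because no
  arm asymmetry is reported; the asymmetric case is a configuration switch.
  By default the relapse effect ends at discontinuation, so
  intention-to-treat estimates are genuinely attenuated relative to
  per-protocol ones. The post-discontinuation tail of the relapse process
  is regenerated at the off-treatment rate, which is exact by
  memorylessness of the Poisson process.
* **EDSS trajectories** stay on the half-point grid: a latent worsening time
  (exponential, 0.10/year scaled by the true hazard ratio) raises the score
  by exactly the baseline's threshold step, improvement analogously
  (competing; only the earlier manifests), and visits within 30 days after
  a relapse are transiently elevated by one step — deliberately injected so
  the 30-day relapse-exclusion rule is exercised: a bump can become a
  failed candidate but never a confirmed event. Measurement noise is not
  simulated (see limitations).
* **Visits** are quarterly (mean gap 90 days, SD 20, floor 14) from the
  index day to the last record, plus an index-day EDSS and a pre-baseline
  history consistent with the intended prior-activity category (for
  worsening patients: a reference visit ~11–12 months back, the onset
  visit, and a confirming visit ≥ 6 months later placed clear of the
  relapse-exclusion window). Records last a lognormal span with median
  ~3.1 years and interquartile range ~2.0–4.6 years, the follow-up
  structure of the motivating cohort. These choices make every simulated
  patient eligible by construction, so analysis sample sizes equal the
  configured `n_patients`.
* **The era switch** indexes a configurable fraction of patients before
  day 0; they receive the treated drug with probability one (true score 1),
  are drawn from a sicker subpopulation (higher EDSS and relapse-count
  distributions — confounded inclusion, so their refitted scores pile up
  high with a left tail), and carry an unmeasured 1.6× relapse-rate
  multiplier that no covariate adjustment can remove — the mechanism by
  which the unrestricted analysis acquires bias. Era is modelled at patient
  level (index before/after availability) rather than as a calendar
  simulation, which is the only feature the sensitivity analysis uses.
  Pre-era patients never switch onto a post-era study drug, so the
  restricted analysis excludes them exactly.

### What the generator does not emulate

Real registries carry measurement error and rater variability in EDSS,
missing and irregular visits correlated with disease state, relapse
under-reporting, calendar trends in prescribing, MRI activity (a known
prognostic factor absent here as in the motivating data), and
registry-specific schema quirks. Passing the validation suite therefore
shows that the pipeline is correct under its own assumptions — confounding
on measured covariates, proportional hazards, correctly specified score —
not that those assumptions hold in any particular registry.

## 3. Validation design and problem sizes

The test suite is property-based against the generator's ground truth; the
sizes are chosen so the whole suite runs on one CPU in a few minutes:

* matching equals an independent brute-force greedy oracle on 100 random
  instances (≤ 50 patients per arm), and the weight formulas are checked by
  hand arithmetic;
* a 5,000-patient confounded cohort is balanced below the 10% threshold on
  every covariate by both stabilized IPTW and caliper-0.2 matching;
* effect recovery uses 50 replicates of 4,000 patients with true
  IRR = HR = 0.7: weighted (ATE) and matched (ATT) per-protocol estimates
  have medians in [0.6, 0.8] and ≥ 90% CI coverage;
* type-I error uses 200 null replicates of 2,000 patients (weighted Cox CI
  excludes 1 in 2–9%);
* intention-to-treat attenuation, the pairwise-censoring invariants, the
  event-detector rule table with fuzzing, the positivity KS/bias shifts
  (50 era replicates of 1,500), and byte-identical grid reruns complete the
  suite.

`scripts/acceptance.R` re-runs the main computation from scratch at 3,000
patients (grid) and 1,500 (era experiment) and writes the headline numbers
as JSON.

## 4. Known limitations

Variance estimation treats the propensity score as known; for stabilized
IPTW this is mildly conservative, visible as a type-I error rate below 5%.
The frailty Cox model conditions on pair, not on patient, so matched
hazard ratios remain marginal with respect to individual frailty. Detected
disability events are timed at the onset visit, so detection delay (one
visit gap on average) and visit density shape the effective time scale —
the reason the disability models adjust for visit density. Confidence
intervals are Wald; no bootstrap is provided. Marginal structural models
with censoring weights, recurrent-event relapse models, roving-baseline
re-referencing and composite no-evidence-of-disease-activity outcomes are
out of scope.
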