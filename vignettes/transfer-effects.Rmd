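---
title: "Estimating causal effects of hospital transfer in long-term care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating causal effects of hospital transfer in long-term care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltctransfer)
```

## The scientific problem

Long-term-care (LTC) residents are frequently transferred to emergency
departments when they become acutely unwell. Transferred residents go on to
develop severe permanent physical impairment, severe permanent cognitive
impairment and death at much higher rates than residents who are never
transferred. The causal question is whether the *transfer decision itself*
harms residents, or whether the excess risk belongs to the acute illness
that triggered the transfer — an illness that administrative assessment data
do not record.

`ltctransfer` implements the full analytic machinery for this question on
quarterly (92-day) assessment data, together with a synthetic cohort
generator that realises the confounding structure the question turns on:

* **person-period construction** — eligibility rules, binary time-varying
  exposure (any transfer within a 92-day window), outcome ascertainment in
  the *subsequent* 92-day window, a permanence rule for the impairment
  outcomes, competing-risk handling and censoring rules;
* **descriptive incidence** — rates per 100 person-years, rate ratios, and
  standardized mean differences (SMDs) for baseline balance tables;
* **a marginal structural model (MSM)** — stabilized
  inverse-probability-of-treatment and censoring weights from pooled
  logistic models, cumulated over each resident's history, feeding a
  weighted cause-specific Cox model;
* **a preference-based instrumental-variable (IV) analysis** — the home's
  prior-year transfer proportion as the instrument, estimated by two-stage
  residual inclusion (2SRI): a first-stage logistic exposure model whose
  residual enters the Cox stage as a control function.

The crude, covariate-adjusted and weighted estimators can all adjust only
for what is measured; only the instrument can remove confounding by the
unmeasured acute illness.

## The data model

One row per resident per 92-day period ("assessment row") carries the
RAI-MDS-style scales — the ADL self-performance hierarchy (0–6; 6 = total
dependence), the Cognitive Performance Scale (CPS, 0–6; ≥ 5 = severe
impairment or comatose), CHESS health instability (0–5) — along with
demographic covariates, a binary transfer flag, and vital/discharge status.

`build_person_periods()` turns assessment rows into counting-process rows
`[92k, 92(k+1))`. The exposure of row *k* is any transfer within period
*k*; the event on row *k* is the outcome ascertained in window *k + 1*.
Permanent impairment onset is the first assessment at or above the
threshold (ADL = 6, CPS ≥ 5) with no later observed improvement; a crossing
that is the final observation counts as permanent (a stricter
`require_confirmation` variant is available). Death within a window is a
competing event for the impairment outcomes; when an impairment onset and
death fall in the same window the impairment takes precedence by default
(switchable). Follow-up ends at the outcome, death, administrative
censoring after 20 periods (five years), or discharge without readmission
within 123 days, censored at the discharge period's end. Periods are
half-open `[92k, 92(k+1))` with day 0 = admission; a transfer on a period
boundary belongs to the period that contains its day.

## The synthetic cohort generator

The generator is a discrete-time Bernoulli-hazard model on the same 92-day
grid the analysis uses — simulator and analysis share a clock. Within each
period, in causal order:

1. **Acute illness**: a latent binary episode process. New episodes start
   with probability `p_illness` (modified on the log-odds scale by a
   resident-level normal frailty); ongoing episodes persist with
   probability `p_illness_persist`. Persistence is essential: the analysis
   pairs exposure window *k* with outcomes in window *k + 1*, so a purely
   memoryless illness could not confound that contrast.
2. **Covariate evolution**: bounded random walks for ADL, CPS and CHESS,
   with an illness-driven upward bump in CHESS (so the measured scales
   partially reflect the latent illness, as in real assessment data).
3. **Transfer**: logistic in the home's latent propensity `theta`
   (equally spaced across `theta_range`, the instrument's source of
   variation, assigned independently of resident characteristics), the
   illness indicator, and measured covariates.
4. **Outcomes**: log-linear per-period probabilities for death, physical
   impairment onset and cognitive impairment onset. Death precedes
   impairment evaluation within a period. True causal transfer effects act
   on the window in which the analysis ascertains the outcome: the death
   hazard of period *t* carries the transfer indicator of period *t − 1*,
   and an impairment event of period *t* (which carries the period-*t*
   transfer) becomes visible at the assessment of period *t + 1*. Any
   configuration whose linear predictor pushes a per-period probability
   past 1 is rejected with an error naming the hazard.
5. **Discharge**: a small constant per-period probability, present only to
   exercise the censoring machinery.

The analysis-facing table never contains the illness indicator; it is
emitted only to a separate truth table. All randomness flows from a single
`set.seed(config$seed)` call with a fixed draw order, so identical
configurations are bit-reproducible. A burn-in year per home (transfer
counts among `residents_per_home` hypothetical prior residents) seeds the
instrument's first follow-up year.

### Named scenarios

`sim_scenario()` packages the four study conditions used in the tests:

* **reference** (the `ltc_sim_config()` defaults): transfers are
  predominantly markers of a rare but persistent and highly lethal illness
  (`gamma_illness_transfer` = 6.5, illness log-hazard on death 4.6),
  background transfer propensity is low (`theta_range` = 0.005–0.06), the
  true effect of transfer on death is log-HR −0.5 and the true impairment
  effects are null. Under these defaults roughly 70–80 % of residents are
  ever transferred, the crude ever/never mortality rate ratio is about 5,
  crude and MSM mortality hazard ratios are 4–5, and the IV mortality
  hazard ratio falls below 1 — the signature of severe unmeasured
  confounding with a protective true effect.
* **randomized**: no confounding of any kind; used for null calibration
  and mean-one weight checks.
* **measured_confounding**: no latent illness; CHESS drives both transfer
  (log-odds 0.6) and death (log-hazard 0.25), and the true death effect is
  log-HR +0.3. The crude estimator is biased upward; weighting on the
  measured covariates recovers the truth.
* **strong_instrument**: latent-illness confounding with a wide propensity
  spread (`theta_range` = 0.02–0.25), the regime in which the
  control-function estimator is well identified at moderate sample sizes;
  true death effect log-HR −0.5.

The reference configuration was calibrated, before any tests were frozen,
to the marginal pattern reported for real incident LTC cohorts: about
two-thirds ever transferred, a crude mortality rate ratio near 5 between
ever- and never-transferred residents, and strongly elevated crude and
weighted mortality hazard ratios against a protective instrumented
estimate. One deliberate departure: the illness effects on the impairment
outcomes are kept moderate (log 1.5 and 1.3), which yields crude impairment
rate ratios of about 1.3–1.5 rather than the 2–3 of published tables —
stronger same-period impairment confounding pushes the control-function
estimator into a regime where its approximation bias dominates at
simulable sample sizes (see *Limitations*).

## Estimators

All four estimators return a common `ltc_hazard` object and share the
counting-process Cox core (`fit_cox()`, backed by `survival::coxph`), with
Efron tie-handling by default (a 92-day grid produces heavy ties; Breslow
is available), observation weights, and a cluster-robust sandwich variance
at the home level. Cluster-robust standard errors carry the CR1
small-sample factor G/(G−1) and intervals use t(G−1) critical values,
since realistic home counts are modest. Analysis time is days since
admission.

**Crude** and **extended Cox**: the exposure alone, or the exposure plus
the time-varying confounder list, entered directly.

**MSM**: `fit_treatment_models()` fits pooled logistic models over
person-periods — the denominator conditional on the time-varying
confounders, exposure history (previous-period indicator and cumulative
count) and a quadratic follow-up clock; the numerator on baseline
covariates, history and clock only — plus an analogous pair for
discharge censoring. Predicted probabilities of the observed exposure and
of remaining uncensored are clipped to `[1e-6, 1 − 1e-6]`;
`compute_stabilized_weights()` forms the per-period stabilized ratio and
carries it forward as a running product within resident, optionally
truncated at the 1st/99th percentiles (the default for applied use;
truncation trades a small bias for variance, and the recovery simulations
run untruncated). The weighted cause-specific Cox model contains the
exposure and the baseline (numerator) covariates, so the weights — not the
outcome model — handle the time-varying confounding.

**IV / control function**: `compute_instrument()` computes each home's
prior-year transfer proportion, updated yearly (blocks of four periods);
the first follow-up year uses the burn-in history, and homes with no
prior-year residents yield a missing instrument (such rows are excluded
with a warning). `first_stage()` regresses exposure on the instrument and
baseline covariates and reports the instrument's Wald statistic, warning
below |z| = 2. `control_function_cox()` enters the first-stage residual in
the Cox stage; the exposure coefficient is a complier-average effect — the
causal hazard ratio among residents whose transfer is sensitive to their
home's propensity — and is reported as such, without any claim of equality
with the population average effect. The residual is Pearson-standardized by
default: with a rare exposure the raw response residual compresses the
between-home contrast onto a narrow probability scale and the Cox stage's
exposure coefficient explodes; the standardized form keeps recovery
comparable where the instrument is strong and bounded where it is weak
(`residual_type = "response"` restores the raw form). The default
confidence interval is a percentile cluster bootstrap over homes (500
resamples, seedable, resampled copies treated as distinct clusters,
failures counted); `ci = "robust"` gives the cheaper home-clustered
interval.

Instrument diagnostics (`instrument_diagnostics()`) report relevance (the
first-stage Wald statistic and the resident-level correlation), an
exogeneity proxy (SMDs of baseline covariates across extreme
resident-weighted instrument quintiles, ties broken by home id), and
per-quintile outcome incidence.

## A worked run

```{r, eval = FALSE}
cfg <- analysis_config(sim = ltc_sim_config(n_homes = 40,
                                            residents_per_home = 300),
                       iv_ci = "robust", seed = 2)
res <- run_pipeline(cfg)
print(res)
emit_tables(res, "results/")   # table1/table2/table3/forest CSVs
plot(res)                      # forest plot
```

`subgroup_analysis(cfg, "age")` re-runs the full estimator grid within
baseline strata (ADL ≤ 2, 2 < ADL ≤ 4, ADL = 5; CPS ≤ 2, 2 < CPS ≤ 4,
CPS = 5; age < 80, 80–89, ≥ 90 — the last band closing an overlap in the
conventional "≤ 90" notation), skipping strata with fewer than ten events.

## What the simulations show — and what they do not

The test suite validates, among other properties: exact worked arithmetic
for published-table rate ratios, cohort accounting and SMDs; agreement of
the Cox core with brute-force partial-likelihood maximization on small
datasets; recovery of a planted death effect (log-HR +0.3) by the MSM
under measured confounding, with mean-one stabilized weights and near-
nominal interval coverage, while the crude estimator is materially biased;
recovery of a planted protective death effect (log-HR −0.5) by the
control-function estimator under latent-illness confounding, while crude
and covariate-adjusted estimators are biased far upward; and the
qualitative direction pattern under the reference conditions.

The recovery studies run at deliberately reduced sizes — 200 replicates of
1 500 residents in 20 homes for the MSM study, 40 replicates of 6 000
residents in 40 homes for the IV study, and a single 12 000-resident
cohort for the direction pattern — chosen so the full suite completes on a
single CPU while Monte-Carlo error stays small relative to the planted
effects.

Passing these tests shows the estimators do what their theory promises
*under the generator's assumptions*. Real assessment data differ in ways
the generator does not emulate: scales move by jumps after acute events
rather than unit random walks; transfer propensity varies within homes
over staffing and policy changes, so a real instrument is weaker and
possibly confounded by regional case-mix; covariates are missing or
mismeasured; significant-change reassessments break the strict 92-day
grid; and treatment-confounder feedback (transfers changing future
measured covariates) is absent from the default configurations, which is
precisely the structure that separates MSMs from plain covariate
adjustment in applications.

## Numerical choices and edge cases

* Rate CIs use the log-rate normal approximation
  `rate · exp(±z/√events)`, with the exact Poisson (chi-square) interval
  below five events and a zero lower bound at zero events. A rate ratio
  against a zero-event comparison group is reported as undefined (`NA`)
  rather than an error in table output.
* SMDs use the pooled-SD form for continuous variables and the pooled
  binomial-variance form for proportions, reported as absolute values.
* Cox convergence follows `survival::coxph` (tolerance `1e-9`, at most 50
  iterations here); non-convergence returns the fit flagged
  `converged = FALSE` with a warning, and |β| > 10 is flagged as probable
  separation.
* Weight-model fits that leave more than 5 % of treatment probabilities
  pinned at the clipping bounds abort with an error rather than silently
  producing degenerate weights.
* Ever/never transfer status for descriptive rates is read from the full
  assessment table, so a transfer in the resident's final (event) period
  counts. The resident-level framing carries the usual immortal-time
  caveat — under a fully randomized generator it is *not* null — so the
  null-calibration checks use the person-time contrast
  (`cohort_incidence(by = "period")`), which is.
* Pipeline outputs carry a provenance header (an FNV-1a hash of the
  configuration plus the seed) and are byte-reproducible for a fixed
  configuration and seed.

## Limitations

* The control-function estimator is only approximately unbiased for a
  nonlinear outcome model; with an instrument as weak as the reference
  configuration's narrow propensity range, its mortality point estimate is
  directionally right but noisy, and under strong same-period impairment
  confounding it overshoots — quantitative recovery is therefore tested in
  the strong-instrument regime, and reference-condition impairment
  confounding is kept moderate.
* The shared-frailty (random-intercept) Cox variant is out of scope; the
  home-level cluster-robust sandwich is the supported device for
  within-home correlation, in both the weight models and the Cox stages.
* The generator's truth is the conditional per-period log-hazard ratio;
  hazard-ratio noncollapsibility means marginal estimands differ slightly
  under strong covariate effects, which is kept small in the recovery
  scenarios by modest outcome-model coefficients.
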