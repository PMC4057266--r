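---
title: "Methods: deriving and validating termination-of-resuscitation rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and validating termination-of-resuscitation rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torrule)
```

## The problem

Out-of-hospital cardiac arrest (OHCA) has a dismal prognosis, and in EMS
systems where field termination of resuscitation is not permitted (as in
Japan) nearly every arrest is transported to hospital. A
termination-of-resuscitation (TOR) rule is a small conjunction of
prehospital criteria that, when all hold at emergency-department arrival,
identifies continued resuscitation as futile. `torrule` implements the
whole derivation-and-validation pipeline for such rules on Utstein-style
registry data:

1. **registry I/O** — a validated per-patient record schema and its
   mapping to risk-direction-coded model covariates;
2. **a synthetic registry generator** — seeded cohorts emulating the
   published nationwide Japanese cohort (2005–2009, 495,607 adults), so
   the pipeline is fully testable although the real national database is
   not publicly deposited;
3. **logistic modelling** — univariate and 11-covariate multivariable
   logistic regression by IRLS, reporting crude and adjusted odds ratios
   (ORs) with Wald 95% CIs;
4. **rule building** — criteria selection by an adjusted-OR threshold and
   conjunction-rule application;
5. **rule evaluation** — 2×2 diagnostics (sensitivity, specificity, PPV,
   NPV) with Wilson score intervals, criteria-count ROC/AUC, and the
   futility misclassification rate `1 − PPV`.

## The model and the derivation procedure

Each patient contributes 11 covariates in fixed order: age (years), male
sex, unwitnessed by bystanders, unwitnessed by EMS, no bystander CPR,
noncardiac etiology, unshockable initial rhythm, no prehospital
defibrillation, no prehospital return of spontaneous circulation (ROSC),
call-to-response time and call-to-hospital time (minutes). Booleans are
*risk-direction coded*: the absence of the favourable feature codes as 1,
so every OR above 1 points toward death. Age and times enter per unit.

The outcome model is ordinary logistic regression,

$$\operatorname{logit} P(\text{death at one month}) = \beta_0 + \sum_{j=1}^{11} \beta_j x_j ,$$

fitted by maximum likelihood. Rule derivation selects every **binary**
covariate whose adjusted OR ($e^{\beta_j}$) is **strictly greater** than a
threshold (default 2.0), ordered by descending OR. On the published
development-group model this yields exactly three criteria — no
prehospital ROSC (OR 25.8), unshockable initial rhythm (2.76), unwitnessed
by bystanders (2.18) — the emergency-department rule `ed_tor_rule()`. The
established prehospital BLS comparator rule (`bls_tor_rule()`) is
unwitnessed by EMS, no shock given, no prehospital ROSC; "no shock given"
maps to the registry's single prehospital-defibrillation field (EMS or
public AED), the only defibrillation field in the schema.

Design choices that were genuinely open:

* **Ties at the threshold are excluded** — the selection is "strictly
  greater than".
* **Selection always uses the one-month-death model**; the derived rule is
  then *evaluated* against both death and unfavorable neurological outcome
  (Cerebral Performance Category 3–5).
* **Continuous covariates are never rule criteria** and no dichotomization
  search is attempted: a cut-point search would be a different (and much
  larger) model-selection problem.
* **No pre-exclusion of EMS-witnessed arrests** before applying the
  derived rule: the rule is evaluated on the full eligible cohort, and
  EMS-witnessed status simply fails the BLS rule's first criterion.
* Whether published *crude* ORs for age and the times were computed
  per-unit or per-category is not stated anywhere we could check; we fit
  them per unit, consistent with the per-unit adjusted ORs.

## The IRLS engine

`fit_logistic()` is a from-scratch iteratively reweighted least squares
maximizer with step-halving, so the log-likelihood trace is provably
non-decreasing (a property test asserts this). Numerical choices:

* **Convergence** is declared when the score norm drops below
  `tol * max(1, sum(w))` with `tol = 1e-8`, where `w` are the IRLS
  weights. The raw score scales linearly with the sample size, and at
  n = 200,000 its floating-point evaluation error alone is of order
  1e-9, so the tolerance is scaled by the effective sample size rather
  than applied to the raw norm. `max_iter = 50`.
* **Covariance** is the inverse observed Fisher information at the
  optimum; CIs for ORs are Wald intervals on the log scale,
  `exp(beta ± 1.96 SE)`, matching the symmetric-on-log-scale look of
  published regression tables.
* **Perfect separation** (a coefficient diverging past 30 on the log-odds
  scale, or a numerically singular information matrix) and
  **rank-deficient designs** (collinear columns are named) raise explicit
  errors rather than returning garbage.
* **Zero cells in a crude 2×2**: the univariate MLE is infinite, so the
  crude OR is reported as `NA` with a separation warning. We deliberately
  apply no automatic continuity correction — silently fabricating a
  finite estimate is worse than an honest `undefined`.

On every non-degenerate 2×2 table the univariate binary fit equals the
closed-form cross-product ratio `ad/bc` to below 1e-6 relative error, and
the multivariable fit is cross-checked against `glm()` in the test suite
(the oracle, never the implementation).

## The synthetic registry generator

The real national database cannot be redistributed, so
`generator_config()` + `generate_records()` emulate it. What the defaults
encode — all taken from the published validation-year (2009) cohort
characteristics:

| quantity | default | unit |
|---|---|---|
| male / bystander-witnessed / EMS-witnessed | 58.0 / 38.5 / 5.0 | % |
| bystander CPR / cardiac etiology | 48.7 / 57.0 | % |
| shockable rhythm / defibrillation / prehospital ROSC | 7.8 / 10.7 / 6.1 | % |
| age median (IQR) | 77 (65–85) | years |
| call-to-response median (IQR) | 7 (5–9) | min |
| transport gap median (IQR) | 23 (19–28) | min |
| true ORs of the outcome model | published adjusted ORs | — |
| target death rate | 95.66 | % |
| survivor CPC 1–2 share | 47 | % of survivors |

Modelling conventions where the publication gives only marginals:

* **Dependence structure** is a shallow causal chain — bystander-witnessed
  → bystander CPR; shockable rhythm → defibrillation → prehospital ROSC —
  with each link parameterized by `P(child | parent = TRUE)`
  (defaults 0.60, 0.85, 0.20); `P(child | parent = FALSE)` is solved from
  the configured marginal, so marginal prevalences are preserved exactly
  in expectation. All other covariates are independent. Any richer joint
  distribution would be invention; the chain keeps the joint explicit and
  configurable.
* **Witness status** is drawn as one three-way category
  (bystander / EMS / unwitnessed), making the two witness indicators
  mutually exclusive as they are on an Utstein form.
* **Age** is a reflected log-normal (reflection point 100 years) matched
  to the median and quartiles, rounded to whole years and truncated to
  18–110 by resampling — the published quartiles are left-skewed toward
  old age and the reflected log-normal reproduces that skew almost
  exactly on the log scale.
* **Times**: call-to-response is log-normal matched to its median/IQR;
  call-to-hospital is call-to-response **plus** a log-normal transport
  gap, which enforces the schema invariant (hospital arrival after scene
  arrival) by construction. The marginal call-to-hospital quartiles are
  therefore approximate (a sum of log-normals is not log-normal); the
  generated median lands within about a minute of the published 30.
* **Outcome**: death is Bernoulli per record with
  `logit(p) = intercept + Σ log(OR_j) x_j`; survivors draw CPC 1–4 from
  `cpc_split` (non-survivors are CPC 5 by definition, which preserves the
  "death implies unfavorable" invariant by construction). `cpc_split`
  defaults put 47% of survivors in CPC 1–2, reproducing the published
  2.04% favorable / 4.34% survival ratio. Survivor CPC is independent of
  the covariates — a simplification; the published unfavorable-outcome
  model has its own (different) coefficients which we do not separately
  emulate.
* **Intercept calibration** (`calibrate_intercept()`): the
  population-averaged death probability is strictly increasing in the
  intercept, so a bracketing bisection on `[-40, 40]` converges; the
  average is taken over a 50,000-patient covariate sample drawn from a
  private RNG stream derived from the configuration seed (so calibration
  never perturbs the generation stream), to an absolute tolerance of
  1e-4 on the rate, with an iteration cap that errors reporting the
  bracket.

**What passing tests do and do not show.** The generator matches the
published *marginals*, a chosen dependence chain, and the published
*conditional* effect sizes. Real registry data have secular trends,
regional EMS heterogeneity, misclassified etiologies, missing data and
covariate interactions, none of which are modelled. Tests passing on
synthetic cohorts therefore validate the *machinery* (estimation,
selection, evaluation), not the clinical transportability of any rule.

## Evaluation choices

* **Wilson score intervals** for all proportion metrics. The choice is
  deliberate: on the published validation-group death table the Wilson
  interval uniquely reproduces the printed specificity CI
  (0.894, 0.911) — a symmetric Wald interval rounds the upper bound to
  0.912. A small number of printed bounds (8 of 48) differ from Wilson
  recomputation by one unit in the third decimal; the original analysis
  software's interval method is unstated, and recomputation from the
  printed 2×2 counts is the package's source of truth.
* **Undefined metrics** (zero denominator) are explicit `NA` markers with
  the metric named, never silent zeros — degenerate cohorts arise
  routinely in simulation.
* **ROC/AUC** uses the ordinal criteria-count score (0..number of
  criteria), computed as the Mann–Whitney rank statistic
  `P(score_pos > score_neg) + P(equal)/2` (identical to trapezoidal
  integration of the discrete ROC), with a Hanley–McNeil variance
  approximation for the CI. The published AUCs (e.g. 0.874 for validation
  death) cannot be recovered from any printed table: the binary
  fulfilled/not-fulfilled rule has one-point AUC
  `(sens + spec)/2 ≈ 0.749`, so the published values must use a richer
  score over per-record data we do not have. The AUC machinery is instead
  verified by an all-pairs enumeration oracle, the exact one-point
  identity, and a cross-check against an independent ROC implementation.
* **Rounding for display** follows the field's tables: proportions to 3
  decimals, percentages to 1 decimal.

## Problem sizes

The test suite works at deliberately modest scales — cohorts of a few
hundred to 100,000 records for marginal-fidelity checks, 400,000 for the
Monte-Carlo calibration oracle, and one 200,000-record cohort for
parameter recovery — chosen so the whole suite runs in well under a
minute while keeping every stochastic assertion at 3–4 standard errors of
slack. The parameter-recovery run (`scripts/acceptance.R`) regenerates a
200,000-record cohort and refits the 11-covariate model from scratch at
each invocation.

## Known limitations

* Survivor CPC is independent of covariates; only the death model's
  effect sizes are emulated.
* The generator emits already-eligible records; the original cohort
  assembly (the ~9% excluded) is not modelled, and its exact exclusion
  criteria are not enumerated in the source material.
* No ALS TOR comparator rule, no decision-curve or cost analysis, no
  penalized regression, interactions, or model selection beyond the fixed
  11-covariate set.
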