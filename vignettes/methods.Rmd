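---
title: "Methods: simulated counter-verification and audit targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated counter-verification and audit targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# Chunks are illustrative; the quantitative claims in the text are the ones
# re-computed by the package's test suite and by scripts/acceptance.R.
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Performance-based financing (PBF) programs pay health facilities a quarterly
bonus proportional to the quantity of services they report. Because payment
follows the report, facilities have an incentive to over-report, and programs
respond with *counter-verification*: auditors re-count a facility's registers
and the bonus is recomputed from verified counts. Auditing every facility
every quarter is expensive, so the operational question is **which facilities
to audit**. This package provides a laboratory for that question:

1. a synthetic generator of facility-quarter reporting panels with a
   configurable over-reporting process (`sim_config()`, `generate_panel()`);
2. a labeling rule that turns reported and verified bonuses into a binary
   over-reporting flag (`label_panel()`);
3. the audit-targeting approaches to compare: random and prior-offender
   sampling strategies (`plan_srs()`, `plan_stratified_srs()`,
   `plan_offender_mixed()`, `plan_offenders_first()`) versus supervised
   classifiers that rank facilities by predicted risk (`fit_classifier()`,
   `plan_model_ranked()`);
4. evaluation machinery (cross-validation, train-on-Q1/predict-later
   protocol, Monte-Carlo detection yield) and a linear audit cost model
   (`per_facility_cost()`, `total_cost()`).

## Labeling rule

For each facility-quarter the quantity bonus is the inner product of nine
service counts with a unit price schedule (`compute_bonus()`). A quarter is
labeled *over-reported* when

> reported bonus ≥ (1 + threshold) × verified bonus,

with threshold 0.10 by default and an **inclusive** boundary: exactly +10% is
flagged. A quarter with verified bonus 0 but a positive reported bonus is an
infinite relative excess and is flagged when `zero_verified_rule = TRUE`
(default). Because `1.1 * 100 > 110` in double arithmetic, the comparison
uses a relative tolerance of `1e-9 * max(verified, 1)`; without it the exact
boundary case mislabels.

Prices are program-specific and therefore fully configurable. The defaults
(`price_schedule()`) are plausible magnitudes chosen so a typical facility's
quarterly bonus lands in the $1,500–$2,000 range; the label is invariant to
rescaling all prices by a constant (tested).

## The generator

`generate_panel()` simulates `n_facilities` (default 140) across PBF and
non-PBF districts (defaults 10 and 8 districts; 3:1 facility split), four
quarters, nine incentivized indicators. Verified ("true") counts are negative
binomial with a facility size factor; covariates include facility type,
managing authority, urban/rural/peri-urban location, log-normal catchment
population, establishment year and staffing.

**Gaming classes.** Each facility games (over-reports) in 0–4 quarters; the
class distribution `type_probs` defaults to (81, 32, 12, 9, 6)/140 — a 57.9%
never-gaming share and ~19.1% facility-quarter prevalence.

**Quarter placement.** Given that a facility games in *k* quarters, the
subset of quarters is drawn from a Gibbs-type subset model: a size-*k* subset
*S* of {1,2,3,4} has probability proportional to `w^a(S)` where `a(S)` counts
adjacent quarter pairs in *S*. A single weight `w > 1` makes gaming streaky
(persistent), `w = 1` makes placement exchangeable, `w < 1` makes it
anti-persistent. `w` is solved by `uniroot()` (on `log w`, bracket
`[log 1e-8, log 1e8]`) so that the model-implied conditional
P(game in Q2 | game in Q1) equals the `persistence` parameter (default
0.577). The calibration targets that specific first-adjacent entry because,
with a fixed class mix, the *time-averaged* adjacent conditional is pinned in
a narrow band by the class counts alone. For the same reason, the
"independence limit" (all conditionals equal to the marginal prevalence)
holds only when `type_probs` is itself Binomial(4, prevalence); the property
test uses binomial class probabilities for that check.
`empirical_persistence()` tabulates the realized conditional matrix.

**Covariate coupling.** `gaming_mechanism` controls how gaming classes attach
to facilities. Classes are drawn first, then assigned to facilities by
ranking a propensity score (plus noise, sd 0.5): `"none"` is random,
`"additive"` is a linear score in the covariates, `"interaction"` is a pure
threshold interaction, `2 · xor(catchment above its median scale, rural)`,
which has no useful linear projection. This gives a controlled experiment:
with the additive mechanism a ridge logistic model matches a random forest;
with the interaction mechanism the forest wins clearly (tested at 600
facilities on the covariate feature set).

**Reports.** Honest facility-quarters report the verified counts, with small
multiplicative noise (sd 5%) applied *only to counts ≥ 20*: for `v ≥ 20`,
`0.05·v + 0.5 < 0.10·v` strictly, so integer rounding of honest noise can
never reach the 10% labeling threshold. Gamed quarters inflate each
indicator by a factor drawn uniformly from [1.15, 1.60] and take the
`ceiling()`, so the reported bonus is at least 1.15× the verified bonus
whenever the latter is positive; a gamed quarter whose verified counts are
all zero fabricates one unit per indicator, which the zero-verified rule
flags. Consequently **the labeling rule recovers the latent gaming indicator
exactly** — the label is noiseless by construction, which is the main
deliberate idealization of the generator.

### Realism and limits

* Per-quarter prevalence is nearly flat (~19% each quarter, with a small
  mid-quarter elevation from the adjacency weighting); real programs show
  quarter-to-quarter variation that this symmetric placement does not
  reproduce.
* The label equals the latent gaming flag deterministically; real
  counter-verification has measurement error on both sides.
* A direct consequence of the labeling rule is that the over-reporting label
  is (nearly) **linearly separable in the reported and verified count
  features**: the label is defined by a ratio of two linear functions of
  those features, so any well-regularized linear model achieves near-perfect
  cross-validated accuracy on the `"basic"` feature set. Nonlinear
  classifiers can therefore only show an advantage through the covariate
  channel — which is why the mechanism-contrast property above is evaluated
  on the `"covariates"` feature set with the facility-level "ever flagged"
  target (base rate ~42%), not on count features. Any benchmark built on a
  counter-verification-style label shares this circularity.
* Counts are cross-sectionally independent negative binomials given the size
  factor; no seasonality, stock-outs, or district-level shocks.

## Evaluation machinery

* `classification_metrics()` computes accuracy, per-class precision/recall
  (reported `NA` when a class is absent from the truth), macro-F1 (per-class
  F1 set to 0 when precision or recall degenerates), and trapezoidal AUC
  over the score-swept ROC. The AUC matches `pROC` to 1e-10 in tests and is
  invariant to monotone score transforms.
* `make_folds()` builds class-stratified, globally balanced folds (works at
  the leave-one-out boundary); `kfold_cv()` averages metrics across folds;
  `grid_search()` runs the hyperparameter grids over shared folds with a
  first-maximum tie-break toward the simpler setting.
* `cross_quarter_protocol()` fits on quarter 1 and predicts quarters 2–4
  without refitting — the deployment-style protocol for a program that can
  only label the past.
* `sampling_yield()` estimates a strategy's expected detection yield (share
  of flagged facilities captured by the audit sample) over `reps`
  independent seeded draws; for SRS this converges to the hypergeometric
  mean (tested).

## Model families and grids

Four families with their tuning grids: naive Bayes (single normal, kernel
density, or supervised equal-frequency discretization — implemented
in-package, cross-checked against `e1071::naiveBayes` for the Gaussian
case), logistic regression with ridge penalty {0, 1e-5, 1e-4, 1e-3, 1e-2}
(`stats::glm` / `glmnet`), SVM with linear, polynomial (degree 2, 3) and
radial kernels, γ ∈ {0.001, 0.01, 0.1, 1} (`e1071`, scores mapped through
the logistic of the decision value), and random forest with ntree ∈
{50, 100, 200, 500}, mtry 1–9 (`randomForest`).

## Cost model

Auditing n facilities when a fraction p of audited facilities is caught
over-reporting costs

> `tc = n · [ p·(mc − s) + (1 − p)·mc ] + fc`,

with marginal audit cost `mc`, recovered sanction `s` (the withheld quarterly
bonus) and fixed cost `fc` (per facility: `afc = fc / n`). Per facility this
is `mc − p·s + afc`, linear and decreasing in the detection rate: with
`mc = 800`, `s = 1900`, `afc = 1600`, a detection rate of 0.19 costs $2,039
per audited facility and a rate of 0.88 costs $728 — a 64.3% saving
(`relative_savings()`; these are the worked numbers in the test suite).

## Determinism and numerics

Every stochastic routine takes an explicit seed and runs under
`withr::with_seed()`, so nothing perturbs or depends on the caller's RNG
state. Pipeline stages derive independent substreams from one master seed
via a Lehmer step (`(seed · 48271 + i) mod 2³¹−1`, kept in double precision
before the integer cast to avoid overflow). Run manifests record an MD5 hash
of the serialized configuration, the seed and the package version;
`run_full()` is byte-reproducible given the config.

## Typical problem sizes

The defaults mirror a small national pilot: 140 facilities × 4 quarters
(560 facility-quarters), 9 indicators, 70-facility (50%) audit samples,
10-fold cross-validation, 1,000 Monte-Carlo draws for sampling yields.
Calibration property tests in the suite use 5,000–20,000 facilities; the
mechanism contrast uses 600. A full default `run_full()` completes in well
under a minute.
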