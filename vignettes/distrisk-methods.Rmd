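---
title: "Distributional risk prediction: model, imputation and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional risk prediction: model, imputation and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(distrisk)
```

# Why distributions of risk

A point estimate of mortality risk averages over everything the model does
not know about a patient. `distrisk` makes two of those sources of
ignorance explicit and propagates them into a per-patient *distribution*
of predicted risks:

1. **unmeasured covariates** — above all serum lactate and albumin, which
   are strong mortality predictors but frequently not yet measured when a
   risk estimate is wanted; and
2. **coefficient uncertainty** — the finite-sample imprecision of the
   fitted model itself, inflated appropriately for the information lost to
   missing data.

The spread of the resulting distribution (summarized as the *risk
distribution range*, the width between the 2.5th and 97.5th percentile of
a case's risk samples) approximates a 95% credible interval when all
covariates are observed, and widens towards a prediction interval when
labs are imputed prospectively. It does **not** capture uncertainty about
variables that are never measured, nor uncertainty over the model
specification itself; competing specifications with different covariates
or interactions are out of scope.

# The risk model

The outcome is in-hospital death (death before postoperative day 60;
patients still in hospital on day 60 count as discharged alive). The model
is a binomial GAM with logit link:

* **Continuous covariates** (age, heart rate, systolic pressure, sodium,
  potassium, white cell count, creatinine, BUN, lactate, albumin, GCS)
  enter as penalized B-splines: 10 second-degree basis functions per
  variable, boundary and interior knots linearly spaced over the training
  range. Smoothness is governed by a second-difference penalty on the
  basis coefficients, the discrete analogue of an integrated
  squared-second-derivative penalty. GCS is treated as continuous despite
  its ordinal scale because its support (3–15, with a median of 15) makes
  a spline the more parsimonious encoding.
* **Discrete covariates** (ASA grade, cardiovascular and respiratory
  status, arrhythmia, CT performed, soiling, malignancy, the 13+1
  surgical-indication categories, and the lactate/albumin missingness
  indicators) are dummy-coded with the base category excluded; an L2
  penalty shrinks inter-category differences.
* **Tensor-product interactions**: heart rate × arrhythmia,
  BUN × creatinine, cardiovascular × respiratory status, and CT-performed
  crossed with soiling, malignancy and indication. A tensor block is the
  set of all column-wise products of the two marginal bases; its penalty
  is the Kronecker sum of the marginal penalties.

The missingness indicators are retained as covariates by default
(removable via `default_gam_spec(include_missingness_indicators =
FALSE)`): whether a lab was measured at all may itself carry prognostic
signal, and keeping the indicators lets the data decide.

## Fitting and numerics

Fitting is penalized maximum likelihood by iteratively reweighted least
squares. Two numerical choices matter:

* **Identifiability ridge.** Each spline block's basis sums to one, so its
  constant direction aliases the intercept, and the curvature penalty does
  not act on that direction. A fixed ridge of `1e-6` on the whole penalty
  pins the decomposition; it changes the fitted surface by far less than
  estimation error, and the unidentified directions it regularizes are
  exactly the directions along which the linear predictor is invariant, so
  predictions and posterior risk draws are unaffected.
* **Step-halving.** Plain IRLS is not monotone in the penalized
  likelihood and can diverge when fitted probabilities pin against the
  working-weight floor; candidate steps are halved towards the previous
  iterate until the penalized likelihood does not decrease. Convergence is
  declared when the relative change in penalized log-likelihood falls
  below `1e-6` (cap: 100 iterations); non-convergence is returned as a
  flagged fit with a warning, never silently.

The coefficient covariance is the inverse of the penalized information
matrix at convergence, which doubles as a Gaussian approximation to the
coefficient posterior.

**Penalty weights** default to 1 per term. The original development
workflow for models of this kind tunes penalties by manual inspection of
partial-dependence plots, which is not automatable; `select_penalty_gcv()`
offers a deviance-based GCV search over a global multiplier as the
reproducible stand-in, and per-term weights can be overridden on the term
specs. On the synthetic cohorts used in the tests, GCV is flat around the
default.

**Backward elimination** (`backward_eliminate()`) scores each candidate
variable by a joint Wald chi-square over *all* its design columns,
including any tensor blocks it participates in — treating a variable's
main effect and interactions jointly — and repeatedly removes the variable
with the largest p-value. It is deterministic given the data.

# Preprocessing

Continuous variables are Winsorized at the 0.1 and 99.9 percentiles of the
*training* data (linear interpolation between order statistics — the same
percentile convention is used everywhere in the package); age is clamped
from above only, since young adults are legitimate data. Thresholds are
refit per cross-validation round and applied, never refit, to validation
and prediction inputs; spline evaluation clamps to the training knot range
for the same reason. Physiologically implausible values (configurable
per-variable ranges on the `variable_spec`s) are redacted to missing
before any modelling. The raw ECG category collapses to a binary
any-arrhythmia flag, and the raw surgical indication is consolidated to
the 13 most common categories plus "other"; an empty or multiple-selection
indication maps to missing and is imputed (the mechanism behind the
registry's 22.6% indication missingness is a preprocessing artefact whose
exact rule is not public, so the package treats it as a configurable
consolidation step).

# Two-stage multiple imputation

**Stage 1 — routine covariates.** Chained equations over the routinely
measured non-nominal covariates: proper Bayesian linear-regression draws
(residual variance from a scaled inverse chi-square, coefficients from
their Gaussian posterior) for continuous targets, logistic coefficient
draws with Bernoulli sampling for binary targets; ordinal statuses are
imputed on the linear scale and rounded to valid levels. Ten cycles, visit
order of increasing missingness, predictors are the other routine
non-nominal covariates, both lab-missingness indicators, and — by default —
the outcome, whose omission would bias covariate–outcome associations
towards the null among imputed rows. Nominal variables (soiling,
malignancy, indication) are completed afterwards by sampling from a
fitted multinomial-logistic conditional model — a probabilistic draw, not
a modal assignment. The number of first-stage imputations follows the
rule `m = ceiling(100 × fraction of incomplete cases)` (minimum 1), so
27.2% incompleteness yields 28 imputations.

**Stage 2 — lactate and albumin.** Each completed dataset gets its own
Gaussian GAM sub-model per lab, with spline terms for the continuous
routine covariates and dummy blocks for the discrete ones. Neither lab is
a covariate of the other (both may be unmeasured simultaneously at
prediction time), and the outcome is excluded by default so the sub-models
can run prospectively (`include_outcome_in_lab` restores it for
sensitivity analysis). Lactate is modelled on the log scale — its marginal
is right-skewed and the Gaussian fit is visibly better — and
back-transformed on draw; this is config-reversible. Each of `k_lab = 3`
imputations samples one coefficient vector from the sub-model posterior
and then draws each missing value from the resulting predictive
distribution. Residual noise is included by default: proper imputation
requires the full posterior predictive, not just coefficient uncertainty;
`lab_residual_noise = FALSE` gives the coefficient-only behaviour for
comparison, since published descriptions of this step are ambiguous about
the residual term. Drawn values are clamped to the lab's Winsor
thresholds.

The result is `m × k` completed datasets; a GAM fitted on each is pooled
by **Rubin's rules** (mean coefficients; mean within-fit covariance plus
`(1 + 1/m)` between-fit covariance), so pooled variances are never smaller
than the average within-fit variances, with equality exactly when the
imputations agree.

# Prediction

For a new case, the routine covariates must be supplied — prospective
imputation covers only lactate and albumin. For each first-stage
imputation's sub-model pair and each of `k_lab` posterior-predictive lab
draws, `n_coef_draws = 5` coefficient vectors are sampled from the pooled
posterior and turned into risks, giving `m × k × 5` samples per case (420
under the 28 × 3 × 5 headline configuration). Complete cases pass the same
completed version through the full grid, keeping sample counts uniform;
their variation comes from the coefficient draws alone. Keeping one
sub-model pair per first-stage imputation (rather than collapsing to a
single pair) preserves between-imputation model uncertainty in the
prospective pathway at no extra fitting cost.

Summaries use the shared percentile convention; the display density is a
Gaussian KDE with boundary reflection at 0 and 1 (bandwidth by Silverman's
rule), which keeps all probability mass inside the unit interval and
integrates to one on the grid to within 1%. An all-identical sample set is
rendered as a spike with a warning rather than an error.

# Validation harness

Cross-validation is grouped by hospital: 80% of hospitals (not cases) form
each development set, the rest validation, repeated 120 times by default;
a case always follows its hospital. Every round refits Winsor thresholds,
imputation sub-models and the GAM on development cases only. Validation
cases missing any baseline covariate are excluded from scoring *for both
models*, mirroring a complete-case comparator's constraints; the
comparator itself is a re-fitted complete-case logistic regression on a
configurable covariate list.

Point scores are AUROC (midrank concordance, ties credited one half), log
loss (natural log, probabilities clipped to `[1e-15, 1 − 1e-15]`), Brier
score, and Tjur's discrimination coefficient. A distribution-predicting
model is scored as the mean of its per-sample scores. Calibration is a
logistic regression of the outcome on a natural-spline basis (4 df) of the
logit of the predicted risk; the mean absolute calibration error averages
|curve − identity| over an equally spaced grid spanning the central 99% of
predictions, weighted by the empirical density of the predictions — tails
where the model rarely predicts contribute little, reflecting that
calibration cannot be assessed where predictions are absent. Per-split
scores are aggregated as medians with 2.5/97.5 percentile intervals, plus
within-split paired differences against the baseline; risk distribution
ranges are reported stratified by which labs were imputed (none /
albumin-only / lactate-only / both).

# The synthetic cohort generator

Real registry data of this kind is not shareable, so the generator is a
first-class module, not a test hack. It emulates:

* the registry's marginal summaries — log-normal right-skewed labs
  (lactate, creatinine, BUN, white cell count), normal marginals
  elsewhere, parameterized from published median/IQR pairs; category
  frequencies for the discrete variables;
* correlation through a latent per-case severity factor loading on ASA,
  heart rate, lactate, BUN, GCS and related variables — this is what makes
  imputation informative;
* a multi-hospital structure (186 hospitals by default, unequal sizes,
  Gaussian intercept offsets of SD 0.2 on the logit scale);
* a known smooth risk function: U-shaped sodium effect, monotone
  log-lactate effect, declining albumin effect, linear age and heart-rate
  effects, ASA steps, and a heart-rate × arrhythmia interaction, with the
  intercept calibrated by root-finding to the 11.3% prevalence target;
* per-variable missingness at the registry rates (lactate 36.4%, albumin
  59.3%, indication 22.6%, others ≤ 1.9%), with the lab missingness
  depending on observed severity markers (ASA, heart rate) under the
  default `"MAR-severity"` mechanism — never on the lab's own value — and
  everything else missing completely at random. Indication missingness is
  injected as MCAR because the registry's true mechanism is a
  non-public preprocessing artefact.

What it does **not** emulate: the joint dependence structure of real
perioperative data beyond a single severity factor, temporal trends in
mortality or albumin recording (dates are absent even in the source
registry extract), repeat-laparotomy dependence between cases, and
deaths after discharge. Passing tests on synthetic data therefore
demonstrate that the machinery is correct and well-calibrated *under the
stated generative assumptions*, not that the published real-data
performance figures transfer.

# Problem sizes and reproducibility

The test suite runs the full pipeline at reduced sizes chosen to exercise
every code path while keeping the suite quick: parameter recovery and
calibration checks on a 20,000-case cohort (the model recovers the
generative logit surface with mean absolute error well under 0.15, and the
calibration error against the generator's own risks is under 0.02);
uncertainty and case-study behaviour on a 6,000-case, 30-hospital cohort
with a 2 × 2 imputation grid; harness integrity on a 12-split, 20-hospital
cross-validation; and the 28 × 3 × 5 headline arithmetic on a 2,000-case
cohort, where it is structural rather than statistical. A single master
seed streams purpose-specific sub-seeds (generation, missingness, each
imputation chain, lab draws, coefficient draws), so any component is
reproducible in isolation and full runs are reproducible end-to-end.

# Known limitations

* The Gaussian approximation to the coefficient posterior is exact only
  asymptotically; with heavy penalties it is a posterior *given* the
  chosen penalties.
* Chained-equation draws for strictly positive covariates are made on the
  raw scale and can, rarely, produce implausible values; the subsequent
  Winsor clamp bounds their influence on the model but not on the
  imputation chain itself.
* The complete-case logistic baseline is a generic comparator on a
  configurable covariate list, not a re-implementation of any published
  calculator's exact equation.
* The rdr is a within-model uncertainty statement; structural
  uncertainty (model specification, cohort shift, never-measured
  determinants of risk) is outside it.
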