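---
title: "Methods: explainable personalized physiological age"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable personalized physiological age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

physage estimates a *personalized physiological age* (PPA) from routine
laboratory biomarkers and explains it variable by variable. This vignette is
the package's account of the underlying models and of the design choices
made where more than one reasonable implementation existed. All empirical
statements below are the ones computed by the package's test suite and by
`scripts/acceptance.R`; nothing here reports a result the shipped code does
not itself reproduce.

## The model

A gradient-boosted tree ensemble (XGBoost) is trained to predict
chronological age from 20-50 continuous biomarkers. PPA is *defined* as the
model's prediction: a 61-year-old predicted 49 has the physiology the model
associates with a 49-year-old. Missing biomarker values are routed natively
by the trees, so the age model consumes unimputed data; the iterative
imputer exists for the comparator metrics, which need complete vectors.

### The age-normalized objective

Cohorts assembled from population surveys over-represent some ages (here,
adolescents about two-fold, with a thinner tail above 70). A plain
squared-error gradient lets the dense ages dominate training, which inflates
errors at the extremes of the age range. The custom objective rescales each
individual's gradient by how badly its own chronological-age group is
currently fitted:

$$grad_i = (\hat y_i - y_i)\cdot
  \frac{\operatorname{mean}_{j \in age_i}\lvert \hat y_j - y_j\rvert}
       {\operatorname{mean}_k \lvert \hat y_k - y_k\rvert + \epsilon}$$

with hessian fixed at 1. Three numerical choices deserve a note:

* **Absolute residuals in both means.** Signed group-mean residuals shrink
  toward zero as the fit converges, which would make the ratio numerically
  unstable exactly when the model is nearly trained. Mean absolute residuals
  keep the ratio a well-behaved measure of group misfit.
* **$\epsilon = 10^{-8}$** guards the denominator at exact convergence.
* **Singleton age groups** use their own absolute residual as the group
  mean; with a single age group the ratio collapses to 1 and boosting is
  ordinary squared-error descent.

The acceptance suite verifies the intended effect: on a cohort with ages
70-79 undersampled five-fold, the ratio of old-age MAE to overall MAE is
smaller under the custom objective than under the standard one (median over
five seeds).

Default hyperparameters are `nrounds = 150`, `max_depth = 3`, `eta = 0.05`,
`subsample = 0.8`, `colsample_bytree = 0.8`, `min_child_weight = 25`. They
were chosen for parsimony: on cohorts of the default generator's scale
(n around 10^4, ~20 variables), deeper or faster-learning settings reach the
same held-out R^2 while attributing up to ten times more spurious
contribution to uninformative variables, which pollutes every downstream
explanation product. `tune_age_model()` provides a small randomized search
for users who want data-driven settings.

## Explanations

Per-variable additive contributions are Shapley values of the trained trees,
computed by an exact interventional TreeSHAP implemented in C++: for an
explained row and one background row, every hybrid root-to-leaf path is
enumerated with closed-form Shapley weights, and contributions are averaged
over the background population. The implementation is verified in the test
suite against brute-force enumeration of all variable coalitions.

Two flavors differ only in the background population:

* **Global**: the background is the whole explained dataset (capped at 200
  rows, drawn deterministically under a seed). The base value is the mean
  model prediction over the background, and base + row sum equals the
  prediction to within float32 accumulation error (< 1e-4 years).
* **Contextualized**: the background is restricted to individuals sharing
  the subject's chronological age. This re-bases every explanation on
  same-aged peers; the row sum is the *PPA deviation* — predicted age minus
  the mean prediction of contemporaries — the package's central metric.
  Positive deviation reads as accelerated aging.

The contextualized flavor is deliberately implemented by restricting the
explanation's *reference population*, not by retraining a predictive model
per age group: retraining would change the predictor being explained, and
the deviations of different age groups would no longer refer to the same
model. Age groups are integer years merged with their nearest neighbours
until each holds at least 50 individuals (per-year granularity where the
data support it). Groups at or below the 150-row background cap use every
member as background, which makes the within-group mean deviation exactly
zero; larger groups use a seeded subsample, trading a fraction of a year of
centering accuracy for compute.

### Dependence profiles and thresholds

Plotting a variable's contextualized contribution against its raw value,
binned by age, exposes the value range where the contribution changes sign:
below it the variable reads "younger than peers", above it "older". The
implementation uses 40 equal-frequency value bins, smooths per-bin means
with a 3-bin moving average (raw per-individual contributions are noisy),
and reports the crossing as the interval spanning the last negative and
first positive bins — the sign change is only localized to within those two
bins, so a clean crossing is at most two bins wide. A crossing is declared
only when the smoothed profile reaches beyond a 0.1-year noise floor on
both sides of zero; without the floor, any flat profile would report a
spurious threshold wherever its near-zero noise happens to flip sign.

## Clustering and signatures

Individuals are clustered on the rows of the contextualized explanation
matrix (chronological age is never a feature) with Ward-linkage
agglomerative clustering on Euclidean distances. `k` defaults to 10 but is
configurable, and `silhouette_report()` gives a silhouette-versus-k table
rather than imposing an automatic selection. Cluster signatures use a
Mann-Whitney test per variable and cluster pair with effect size
$r = |Z|/\sqrt{n_1+n_2}$: exact null distribution for tie-free comparisons
with $n_1+n_2 \le 12$, tie-corrected normal approximation otherwise (the
reported Z carries no continuity correction; the normal-branch p-value uses
the standard 0.5 correction). Benjamini-Hochberg adjustment is applied
across all variables within one cluster pair — the family a reader of one
pair's signature actually inspects — with a pooled-family option. A
variable is retained only with at least a medium effect (r >= 0.3) *and*
adjusted p below 0.05; the effect-size gate deliberately binds even when
the p-value is tiny, so that large samples cannot promote negligible
differences into signatures.

## Reduction and validation

Recursive feature elimination drops the variable with the smallest mean
absolute contribution, refits, and records test-set performance until one
variable remains; the minimal model is the smallest set within 1% relative
R^2 of the full model (test-set R^2, the stricter and simpler reading).
Importance inside the loop uses the fast path-dependent TreeSHAP — only the
ranking matters there — and re-tuning at each step is available behind
`retune = TRUE` but defaults off. Ties in minimal importance drop the
lexicographically last variable, making traces reproducible.

Two classical comparators are implemented on the same variables:

* **Klemera-Doubal (KDM)** in the corrected form: per-biomarker linear
  regressions on age, an age-correlation screen (|r| >= 0.1), and the
  estimator that blends the inverse regressions with chronological age
  weighted by the age-correction variance $s_{BA}^2$ (estimated from the
  spread of the uncorrected estimator minus its expected sampling noise via
  the characteristic correlation). On noise-free linear biomarkers the
  estimator returns chronological age exactly, which the tests assert.
* **Homeostatic dysregulation (HD)**: Mahalanobis distance to a young
  reference population, by default ages 18-30 with all values inside the
  [1st, 99th] percentiles of that stratum, after log-transforming
  right-skewed positive variables (skewness > 2) and standardizing on the
  reference. A near-singular reference covariance is ridge-regularized with
  a warning.

Survival validation cuts a metric at its sample deciles (ties to the lower
decile), takes decile 5 as reference, and fits a Cox proportional-hazards
model adjusted on sex, age, year of inclusion and the age-by-year
interaction, restricted to adults (18+). Linear covariate associations
adjust on age and sex, and AIC differences rank competing metrics.

## The synthetic cohort generator

Every statistical claim above is tested against cohorts with known ground
truth, so the generator is first-class code. Each individual draws an
integer age from a configurable histogram (default: ages 12-20 at twice the
weight of 21-69, 70-79 at three quarters), a sex, a survey year, and one
standard-normal deviation score per variable. A variable's ground-truth
contribution is `amplitude x score` years (zero for null effects and
outside window effects), and its raw value is generated from the
individual's *apparent age* (chronological age + contribution) through the
effect's shape — linear drift, saturating sigmoid with a raw-value midpoint,
age-window, or pure noise — plus baseline heterogeneity and measurement
noise. Missingness is injected completely at random (the package targets
cohorts whose missingness is reported uniform across age and sex; no
informative-missingness mechanism is modelled), and mortality is exponential
under a proportional-hazards model whose log-hazard is linear in the total
true deviation and in age, censored administratively.

Three consequences of this design matter for interpreting tests:

* **Importance tracks precision, not amplitude alone.** For a model
  predicting chronological age, a variable's mean absolute contribution
  scales with how precisely it pins down age — roughly the inverse of its
  total age-equivalent variance (deviation amplitude plus measurement
  noise). A large deviation amplitude with unchanged noise makes a variable
  *less* important to the age prediction. The default and planted panels
  therefore couple larger amplitudes with proportionally lower
  age-equivalent noise, which is also the physiological situation they
  emulate: the dominant aging markers are tightly measured, minor ones are
  noise-dominated. Recovery tests (Spearman between planted amplitude and
  mean |contribution| >= 0.8) are tests of that coupled design.
* **Sigmoid thresholds are age-specific by construction.** A variable can
  only carry age signal if its distribution drifts with age, so the planted
  zero-contribution value (exposed by `planted_threshold()`) moves along
  the age axis; the nominal `center` is the threshold at the cohort
  mid-age (45.5 under the default distribution). Threshold-recovery checks
  therefore read the crossing of an age bin whose mean age is the mid-age.
* **Deviations are the model's residual information, not its error.** The
  generator's default panel is calibrated so the fitted model lands in the
  performance region typical of routine-biomarker age models (held-out R^2
  around 0.8, MAE around 6.5 years on the default 10,000-individual cohort);
  the gap to perfect prediction is exactly the physiological deviation the
  framework is designed to surface.

What the generator does *not* emulate: survey weights, multi-cycle variable
harmonization, correlated biomarker blocks (each variable's deviation is
independent), informative missingness, and non-exponential survival. Tests
passing on these cohorts demonstrate that the machinery recovers planted
structure under its stated assumptions, not that any particular real cohort
satisfies those assumptions.

## Problem sizes and determinism

The shipped tests and the acceptance script use cohorts of 2,000-20,000
individuals with 5-20 variables: large enough for stable recovery of the
planted structure, small enough for an interactive workflow. Every
stochastic step (generation, splitting, subsampling, training) takes an
explicit seed, xgboost runs single-threaded, and the interventional SHAP
kernel replicates xgboost's float32 split comparisons, so all pipelines are
bit-reproducible under a fixed seed; the only tolerance is the float32
leaf-value accumulation visible in the 1e-4-year additivity bound.

## Known limitations

* Interventional SHAP cost grows with explained rows x background rows x
  trees; the background caps (200 global, 150 per age group) are the lever
  if larger cohorts are explained.
* The contextualized flavor needs enough individuals per age group;
  explaining a handful of individuals of one age against themselves is
  degenerate (a minimum group size of 2 is enforced, 50 is the default
  before merging).
* KDM's $s_{BA}^2$ estimate can be driven non-positive by strongly
  non-linear biomarkers; the implementation then falls back to the raw
  spread of the uncorrected estimator (floored at 1e-8), which keeps the
  estimator defined at the cost of weaker age anchoring.
* The Mann-Whitney exact branch requires tie-free samples; contributions
  from tree ensembles can tie exactly (identical leaf paths), in which case
  the tie-corrected normal approximation is used even for small samples.
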