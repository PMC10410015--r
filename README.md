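# physage

Explainable personalized physiological age (PPA) from routine laboratory
biomarkers.

Chronological age is a poor summary of an individual's physiological state:
two 60-year-olds can carry the biology of a 50- and a 70-year-old. `physage`
estimates a personalized physiological age as the prediction of a
gradient-boosted tree ensemble trained on chronological age over routine
biomarkers, then decomposes it additively, variable by variable, so that the
estimate is auditable down to each laboratory value. It is aimed at
biostatisticians and epidemiologists working with cross-sectional
survey-style cohorts (one row per individual: age, sex, inclusion year,
20-50 continuous biomarkers, optional mortality follow-up).

The framework provides:

* **An age-normalized training objective.** Boosting gradients are rescaled
  by each chronological-age group's mean absolute residual relative to the
  overall mean, `grad_i = (ŷ_i − y_i) · mean_{j∈age_i}|ŷ_j − y_j| /
  (mean_k|ŷ_k − y_k| + ε)`, so sparse age groups are not sacrificed to dense
  ones.
* **Global and contextualized Shapley explanations** via an exact
  interventional TreeSHAP (own Rcpp kernel, verified against brute-force
  coalition enumeration). The contextualized flavor uses the individual's
  own age group as the reference population; the sum of a row is the **PPA
  deviation** — predicted age minus the mean prediction of same-aged peers.
* **Age-specific biomarker thresholds** from the zero crossings of
  dependence profiles (contribution vs raw value, by age bin).
* **Explanation-space clustering** (Ward/Euclidean) with statistically
  qualified cluster signatures (Mann-Whitney with effect size r ≥ 0.3 and
  Benjamini-Hochberg FDR).
* **Recursive feature elimination** by SHAP importance with the <1%
  relative-R² minimal-model rule.
* **Validation machinery**: decile-based Cox mortality models, covariate
  associations, and the classical comparators Klemera-Doubal (KDM) and
  homeostatic dysregulation (HD, Mahalanobis distance to a young reference).
* **A synthetic cohort generator** with per-variable ground-truth age
  contributions, configurable missingness and a deviation-linked mortality
  process, so every stage can be tested against known truth.

## Worked example

```r
library(physage)

# simulate a cohort with known ground truth
sim <- generate_cohort(generator_config(n_individuals = 5000, seed = 42))
sim
#> Synthetic cohort: 5000 individuals, 20 biomarkers, 533 deaths
#> true deviation: mean 0.26, sd 12.88 years

# prepare: inclusion filters, 80:20 stratified split (trees need no imputation)
flt <- filter_cohort(sim$cohort)
sp <- split_cohort(flt$cohort, test_fraction = 0.2, seed = 1)

model <- fit_age_model(sp$train, objective = "age_normalized", seed = 1)
evaluate_age_model(model, sp$test)
#> R2 = 0.823, MAE = 6.53 years (n = 1000)
```

R² and MAE are computed against chronological age on the held-out set; the
gap to perfect prediction is not all error — it contains the physiological
deviation the framework is built to surface. Explanations make that
deviation per-individual and per-variable:

```r
eg <- explain_global(model, sp$test, seed = 1)
ec <- explain_contextualized(model, sp$test, min_group_size = 25)
ppa <- compute_ppa(eg, ec, sp$test)
head(ppa, 3)
#>     id age      ppa ppa_deviation
#> 1 3448  12 19.74766     0.7820754
#> 2 1883  12 19.42547     0.4598939
#> 3  138  12 10.94066    -8.0249216
```

Individual 138 is a 12-year-old predicted 10.9, reading 8.0 years younger
than the average prediction of other 12-year-olds. Importance ranking and
age-specific thresholds:

```r
head(rank_importance(eg), 5)
#>    variable mean_abs_phi      share cumulative_share
#> 1     hba1c   10.5220420 0.44816653        0.4481665
#> 2   glucose    4.5885790 0.19544187        0.6436084
#> 3       bun    1.6399404 0.06985017        0.7134586
#> 4   albumin    0.8429242 0.03590276        0.7493613
#> 5 uric_acid    0.7504836 0.03196543        0.7813268

dp <- dependence_profile(ec, sp$test, "hba1c", age_breaks = c(12, 40, 52, 80))
dp$crossings
#>   age_bin       lo       hi
#> 1 [12,40) 4.926981 5.047327
#> 2 [40,52) 5.472284 5.553015
#> 3 [52,80] 5.941819 6.057279
#> 4     all 5.395178 5.472284
```

The crossing interval is the raw-value range where the variable's
contribution changes sign for that age group: below it the value reads
"younger than peers", above it "older" — an age-adapted normal threshold.
(The generator planted this variable's mid-age threshold at 5.5.) Finally,
the deviation metric is validated against the simulated mortality process:

```r
ht <- cox_deciles(ppa$ppa_deviation, sp$test)
ht
#> Cox decile model: n = 835, events = 101, AIC = 1217.7
#>  decile   hr   lo    hi  n events unstable
#>       1 1.27 0.34  4.74 84      4    FALSE
#>       ...
#>      10 5.98 2.03 17.68 84     11    FALSE
```

Hazard ratios are adjusted on sex, age, inclusion year and the age-by-year
interaction, with decile 5 as reference; `cluster_explanations()`,
`signature_tests()` and `cluster_decision_profile()` then group individuals
into aging profiles, and `recursive_eliminate()` produces the minimal model.
The methods vignette (`vignettes/physage-methods.Rmd`) documents the models,
defaults and design decisions.

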