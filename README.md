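# playcog

Gameplay telemetry featurization and stacked-ensemble prediction of
preschool cognitive scores.

Routine developmental assessment is rare in low-resource settings because
the benchmark instruments (such as the Bayley Scales, BSID-III) need
trained specialists and hours per child. A promising alternative is a
tablet game battery delivered by non-specialists: the child's taps and
drags are logged with millisecond timestamps, and a supervised model maps
gameplay features to the benchmark cognitive score. playcog is a complete,
tested R implementation of that analysis for researchers in digital
phenotyping and child development:

* a **synthetic cohort generator** with known latent ability θ — game
  engagement, correctness, tempo and the benchmark score all depend on θ,
  so the pipeline's recovery properties are checkable
  (`sim_config()`, `simulate_cohort()`);
* **telemetry featurization**: per-level counts/latencies, derived
  accuracy/playtime/activity features per level, per game and across the
  nine-game battery, meaning-based imputation for missed levels, skewness
  transforms, correlation pruning (|r| > 0.9), pairwise
  interaction terms, a mas-o-menos composite, and PCA components to 70 %
  variance (`assemble_feature_set()`);
* the **learning machinery**: a 70/30 split, repeated 10-fold CV over
  7 feature selectors × 5 learners (each selector capped at 15 features),
  the top 5 models by out-of-fold correlation combined through three
  stacking functions with fixed weights

  `DEEP = 0.25·stack_LR + 0.25·stack_RF + 0.50·stack_XGB`

  (`run_repeated_cv()`, `build_ensemble()`, `predict_deep_scores()`);
* the **evaluation surface**: Pearson r with Fisher-z CI, ICC(2,1) with
  F-based CI, MAE/RMSE/bias, Bland–Altman limits, ROC analysis of
  below-25th-percentile detection at a Youden-style cutoff, exposure and
  fine-motor bias tests, and a floor/ceiling check (`deep_evaluate()`).

Everything is tibble-in/tibble-out and pipe-friendly, with `tidy()` /
`glance()` methods and `autoplot()` for results.

## Worked example

```r
library(playcog)

bundle <- run_pipeline(
  sim = sim_config(n_children = 200), # the default calibrated cohort
  cv  = cv_config(repeats = 2),       # 2 repeats of 10-fold CV
  seed = 42
)
bundle
#> <deep_pipeline> seed 42, 200 children, 438 features
#> <deep_evaluation>
#>   benchmark 25th-percentile threshold: 67  | score cutoff: 69.47
#>   train (n=134): r = 0.626 [0.51, 0.72]  ICC = 0.584  MAE = 3.70 (2.80)  bias = -0.01
#>   test  (n= 56): r = 0.712 [0.55, 0.82]  ICC = 0.611  MAE = 4.06 (2.94)  bias = +0.02
#>   train ROC: AUC = 0.849  sens = 0.774  spec = 0.874  acc = 85.1%
#>   test  ROC: AUC = 0.860  sens = 0.733  spec = 0.878  acc = 83.9%
#>   excluded children: c00045, c00066, c00067, c00070, c00079, c00094, ...
```

Reading this: on a simulated 200-child cohort the ensemble's predicted
("DEEP") scores correlate 0.63/0.71 with the benchmark score on the
training/test children, with ICC(2,1) around 0.6 (good agreement), a mean
absolute error of ~4 points on a 31-point score range, near-zero bias,
and AUC ≈ 0.85 for identifying children below the 25th percentile. Train
metrics are computed from fold-held-out predictions, so they are
comparable with test metrics. Ten children were excluded because they
skipped an entire game that feeds the final model — skipping itself being
an engagement signal, not a missing-data problem.

```r
tidy(bundle$ensemble)[, 1:5]
#> # A tibble: 5 × 5
#>   selector      learner       model                         n_features holdout_r
#> 1 rf_importance random_forest rf_importance_x_random_forest         15     0.672
#> 2 rfe_linear    random_forest rfe_linear_x_random_forest            15     0.669
#> 3 correlation   random_forest correlation_x_random_forest           15     0.667
#> 4 elastic_net   random_forest elastic_net_x_random_forest           15     0.662
#> 5 lasso         random_forest lasso_x_random_forest                 15     0.658

autoplot(bundle$evaluation, type = "bland_altman")
```

`run_pipeline(..., out_dir = "run1/")` additionally writes `report.json`,
`report.md` and `bland_altman.csv`; reruns of the same configuration are
byte-identical.

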