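---
title: "Gameplay telemetry to cognitive scores: the playcog methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gameplay telemetry to cognitive scores: the playcog methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

playcog implements an end-to-end analysis for gamified cognitive assessment
of preschool children: raw tablet gameplay telemetry (timestamped taps and
drags, each scored correct, incorrect or background) is turned into a
feature matrix, a stacked ensemble of feature-selector x learner models is
trained under repeated 10-fold cross-validation to predict a benchmark
cognitive score (the raw BSID-III cognitive subscale score), and the
predicted score — the *DEEP score* — is evaluated for agreement and
discrimination. Because no public dataset of this kind exists, the package
ships a first-class synthetic cohort generator with a known latent ability,
which makes every downstream stage testable and makes parameter-recovery
claims checkable.

```{r, eval = FALSE}
library(playcog)
bundle <- run_pipeline(
  sim = sim_config(n_children = 200),
  cv = cv_config(repeats = 2),
  seed = 42
)
bundle$evaluation
```

## The battery and its event logs

The battery is nine games, each with 2–6 difficulty levels, 40 levels in
total. Games are gesture-typed (tap, drag, or mixed), each level has a 60 s
timer, and a level is completed when five correct responses occur before
the timer, which unlocks the next level. The per-game level counts are not
fixed by any external constraint beyond the reported totals (nine games,
2–6 levels each, 40 levels overall), so the defaults place three levels on
matching shapes and five on jigsaw — the two drag games whose deeper levels
anchor the feature namespace — and are configurable through a YAML override
(`load_schema()`). Timestamps are milliseconds from level start; event logs
are JSON-lines, one level session per line, a deliberately simple format
for a backend whose native dump format is not public.

## The synthetic cohort generator

The generator is a latent-ability model. Each child draws
$\theta \sim N(0, 1)$, and $\theta$ drives four things:

* **Engagement.** Each game is attempted with probability
  $\mathrm{logit}^{-1}(6.888 + 2\theta)$. The intercept was solved by
  numerical integration so that the expected fraction of children
  attempting all nine games is 0.955, the engagement pattern observed in
  the field; the slope of 2 concentrates non-attempts in low-ability
  children, matching the observation that the children who skipped games
  were the lowest scorers.
* **Correctness.** Within an attempted level, a non-background gesture is
  correct with probability
  $\mathrm{logit}^{-1}\!\big((a_g\theta - d_\ell)/\nu\big)$, where $a_g$ is
  a per-game discrimination (defaults 0.8–1.3, highest for the drag
  games), $d_\ell = -1.2 + 0.55(\ell-1)$ makes later levels harder, and
  $\nu$ (`response_noise`, default 1) scales the noise; as $\nu \to 0$
  correctness becomes a deterministic step in ability.
* **Tempo.** Inter-gesture gaps are lognormal with median
  $2e^{-0.25\theta}$ s (dispersion 0.5, floor 0.25 s): abler children are
  faster, so latency and activity features carry signal.
* **Outcomes.** The benchmark score is
  $\mathrm{round}\big(\mathrm{clamp}(\mu + \sigma_y(\rho\theta +
  \sqrt{1-\rho^2}\,\varepsilon))\big)$ on the integer support 57–88 (a
  31-point range), with $\mu = 70$, $\sigma_y = 6$ and $\rho = 0.75$. The
  fine-motor score is the analogous map with correlation 0.5. Smartphone
  exposure is Bernoulli(0.57), independent of everything else — the null
  on which the exposure bias test is calibrated.

$\rho = 0.75$ is a calibration knob, not a claim about children: it places
the fitted pipeline in the regime where test-set correlations come out
near 0.67, the level reported for the field data this design emulates.
Background gestures occur at rate 0.10. Each gesture's outcome stream and
the 10 % background rate are invented where the field literature reports
no distributional facts about raw event streams; they are chosen so that
every statistical structure the analysis assumes (ability-graded accuracy,
latency and attrition, a correlated benchmark, a null exposure effect) is
present, and nothing else is.

What the simulator does **not** emulate: assessor help during demo mode,
fatigue or order effects across games, household context, measurement
error structure of the benchmark instrument beyond rounding, and any
dependence of exposure on ability. Passing tests on simulated cohorts
therefore show that the pipeline recovers the signal its design assumes;
they cannot show that real gameplay contains that signal.

## Feature engineering

Raw ("tablet") features per level: counts of correct/incorrect/total
gestures by type, background events, first/last event timestamps, and the
latency of the first correct response. Derived features follow a fixed
registry: `accuracy_cbyi` (correct over correct+incorrect), `accuracy_cbyt`
(correct over all events), `correctrate` (correct per second of playtime),
`playtime` (last minus first event), `completion_time` (time of the fifth
correct, else the 60 s timer), and `activity` (events per second), computed
per level, aggregated per game (`av_*` means, `total_*` sums, pooled
accuracies, levels played), for the matching-shapes + jigsaw pair
(`msjig_*`), and across all nine games (`sum_all_levels_played`,
`sum_completion_time`, `sum_total_accuracy_cbyt`, ...). The registry is
reverse-engineered from the feature names the DEEP analysis reports; the full in-house
list of 11 types is unpublished, so per-stage column counts are reported,
never asserted.

Missing cells are imputed by meaning, not by statistics: accuracies and
rates of a missed level are 0, completion times and latencies are the full
timer, counts are 0, and game/across-game sums are recomputed from the
filled per-level values — a missed level is treated as maximal failure,
which is the assessment-theoretic reading of non-attempt.

Columns with adjusted Fisher–Pearson skewness above 1 are square-root
transformed (after shifting negative minima to zero); below −1, squared;
each at most once. Features correlating above |r| = 0.9 with an earlier
retained feature are dropped by a greedy left-to-right scan — the
published rule says only that correlated features were dropped, and the
greedy scan is the deterministic completion of that rule. Interaction
terms are the pairwise products and both-direction ratios of a 20-feature
subset (by default the 20 features most correlated with the outcome on the
training rows); candidates with ≥ 15 % null cells (null = either parent
originally missing, or a zero denominator — undefined-before-imputation,
the stricter of the two readings) or correlating above 0.9 with anything
retained are dropped. One mas-o-menos composite (sign-weighted average of
standardized features) and the leading principal components reaching 70 %
cumulative variance complete the set, and everything is standardized.

**Leakage policy.** Every data-dependent quantity — skewness, pruning
correlations, the interaction subset, mas-o-menos weights, PCA loadings,
scaling constants — is fitted on the training children only and applied to
all. The original DEEP analysis describes these transforms before describing
the split, which is ambiguous; fitting on everything is available as the
"paper-like" mode (`run_pipeline(paperlike = TRUE)`), but sound practice
is the default.

## The ensemble

Children are split 70/30 (140/60 at the default cohort size). Seven
selectors (univariate correlation, LASSO path, elastic-net path,
random-forest importance, gradient-boosting importance, linear RFE,
mRMR — the DEEP analysis names seven selectors but not which seven; these are
the seven standard choices) each return at most 15 features; five learners
(linear regression, random forest, SVM, XGBoost, logistic regression)
yield a 35-model grid. Each combination is scored by the Pearson
correlation of its out-of-fold predictions — averaged over repeats of the
10-fold CV — with the outcome. Logistic regression participates by
dichotomizing the training outcome at its 25th percentile and contributing
its predicted probability rescaled to the score range; this is flagged as
an interpretation, since a classifier's role in a score regression is
otherwise undefined.

The top five models by holdout correlation (ties: fewer features, then
name) are refit on the full training set, with feature lists re-selected
on the full training data. Three stacking functions — linear regression,
random forest, XGBoost — are fitted on the five out-of-fold prediction
columns, and the DEEP score is their weighted average with fixed weights
0.25/0.25/0.50, clamped to the score support.

**Train-set evaluation is out-of-sample by design.** Refitting memorizing
learners on the training set and scoring them there would produce
in-sample correlations above 0.9 regardless of generalization, which
cannot be compared with test-set numbers. The training children are
therefore evaluated on fold-held-out stacked predictions (an internal
5-fold CV over the stacker fit on the out-of-fold base-prediction design),
while test children are scored by the refit ensemble. This is what makes
"train and test metrics are comparable" a falsifiable property.

Children who did not attempt an entire game that contributes any
base-model feature are excluded from prediction rather than imputed — a
whole missing game is an engagement signal, not a missing-data problem —
and are listed in the evaluation.

## Evaluation

Agreement: Pearson r with Fisher-z interval; ICC(2,1), the
single-measures absolute-agreement intraclass correlation from the
two-way random-effects ANOVA (Shrout–Fleiss), with the F-based interval
(the original DEEP analysis reports only a 95% CI; the F-based interval is the
standard companion of ICC(2,1)); MAE, RMSE and mean bias
(predicted − benchmark) with SDs — the dispersion printed beside RMSE is
the square root of the SD of squared errors, one of several readings of an
ambiguous table label, and is documented as such. Bland–Altman limits are
bias ± 1.96 SD of differences.

Discrimination: the positive class is a benchmark score strictly below
the training sample's nearest-rank 25th percentile (frozen for test
evaluation; a combined-sample percentile would leak test labels into the
class definition). The cutoff maximizes sensitivity + specificity over
midpoints between sorted unique training scores, taking the lowest on
ties; AUC uses the Mann–Whitney pair-counting construction with ties at
one half. Bias checks: an equal-variance t-test of prediction errors by
smartphone exposure and the Pearson correlation (with r²) of errors with
fine-motor scores. The floor/ceiling analysis counts low scorers
(< 25th percentile) playing fewer than 10 levels and high scorers
(> 90th percentile) not attempting all 40.

## Numerical choices and degenerate inputs

Zero-variance columns: retained by pruning (with a warning), weight 0 in
mas-o-menos, dropped from PCA input, centered-only in scaling. Constant
out-of-fold stacker designs fall back to the mean predictor with a
warning. A level with a single event has zero playtime, so its rate
features are undefined and imputed 0. ICC with zero between-subject
variance is reported as 0 with a warning. All stochastic components
(ranger, XGBoost, fold assignment) are explicitly seeded; a single global
seed fans out to stage seeds by fixed offsets so stages can be rerun
independently.

## Problem sizes used in the test suite

The shipped tests exercise the pipeline at sizes chosen to make sampling
variability, not runtime, the binding constraint: oracle equivalence on
1,000 random 8×2 tables; simulator calibration on 2,000 children;
parameter recovery on one 200-child cohort with 2 CV repeats; null
calibration of the test-set correlation on twenty 200-child cohorts with a
reduced grid (3 selectors × 2 learners, 5 folds — the null property does
not depend on grid size); train/test comparability on ten 200-child
cohorts with 1 repeat; type-I calibration of the exposure test on 1,000
simulated outcome draws scored by the oracle predictor. Multi-seed
properties are asserted on the mean across seeds, which is the calibration
claim itself; single-seed values at n = 60 test children fluctuate with an
SD near 0.15 and are reported, not asserted.

## Known limitations

The per-game level counts, timers and the exact feature-type list of the
original instrument are unpublished; the defaults satisfy every published
constraint but are not the instrument. Learner hyperparameters are fixed,
modest defaults with no per-fold tuning. The generator's event streams are
the simplest model with the required structure, so absolute error
magnitudes (MAE near 3–4 points on simulated cohorts) should not be read
as forecasts of field performance. Exact per-stage feature counts (412/83
interactions at n = 200 in the original DEEP analysis) depend on the unpublished type
list and on the data; the package reports its own composition instead.
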