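# nirssl — class-rebalanced self-training for NIR leaf spectra

`nirssl` classifies leaf nutrient status — five ordinal classes (VL, Low,
Proper, High, VH) of nitrogen or potassium concentration — from 224-band
near-infrared reflectance spectra (942–1680 nm), in the common field
situation where chemistry-labeled leaves are few and heavily imbalanced
while unlabeled hyperspectral pixels are abundant.

The core is an iterative **self-training** loop with **per-iteration class
rebalancing** of the pseudo-labeled data:

1. balance the labeled spectra once with SMOTE;
2. inject unlabeled pixels at the labeled:unlabeled ratio
   β = D_labeled / D_unlabeled;
3. repeat: fit a base classifier (PLS-DA, LDA or random forest) on labeled
   + pseudo data → pseudo-label the pool → keep predictions with max class
   probability ≥ τ → resample the kept set with one of four schemes —
   random (RAS, p_j ∝ C_j), mean (MES, p = 1/k), reverse (RES, p_j ∝ 1/C_j)
   or SMOTE — until the pseudo-labels stabilize.

Class imbalance is quantified by μ = C_max / C_min; MES and SMOTE hold
μ = 1 for the rebalanced set at every iteration, RES drives μ down
gradually. Around the loop the package provides: dot-product similarity
screening of cube pixels against the labeled mean spectrum, Savitzky–Golay
smoothing, ENVI cube and CSV table I/O, macro/weighted precision–recall
metrics (MAP, WAP, WR = micro accuracy) computed from the confusion matrix,
balanced-test-set construction, stratified cross-validation, Gini
wavelength importance (weighted and literal node-difference modes) and
per-band Pearson correlation with concentration — plus a seeded synthetic
generator of labeled spectra and hyperspectral leaf cubes so everything is
testable without the original data.

## Worked example

Simulate a labeled set with the potassium training-division class profile
(29:131:185:289:116, μ ≈ 9.97), an unlabeled pool, and compare the plain
supervised forest against the full rebalanced self-training run:

```r
library(nirssl)

leaves <- simulate_labeled_set(generator_spec(
  class_counts = c(29, 131, 185, 289, 116), seed = 42))
pool <- simulate_labeled_set(generator_spec(
  class_counts = rep(600L, 5), seed = 43))$spectra

supervised <- self_train(leaves, unlabeled = pool, base = "rfc",
                         max_iter = 0, seed = 42)
ssl <- self_train(leaves, unlabeled = pool, base = "rfc",
                  beta = 1/4, tau = 0.8, max_iter = 8,
                  labeled_sampler = "smote", pseudo_sampler = "mes",
                  seed = 42)
ssl
#> Class-rebalanced self-training model
#>   base classifier : rfc
#>   labeled samples : 750 (mu = 9.97; SMOTE-balanced to 1445)
#>   unlabeled used  : 3000 (beta = 0.25)
#>   pseudo sampler  : MES, tau = 0.80
#>   iterations      : 8 (max_iter reached)
```

The history records, per iteration, the high-confidence pseudo-label count
and the imbalance ratio of the rebalanced pseudo set — identically 1 under
MES:

```r
ssl$history[1:3, 1:4]
#>   iteration n_high_confidence n_pseudo mu
#> 1         1                 4        4  1
#> 2         2                 5        4  1
#> 3         3                 7        6  1
```

Evaluation on a balanced held-out set (μ = 1, so WAP = MAP):

```r
holdout <- simulate_labeled_set(generator_spec(class_counts = rep(40L, 5),
                                               seed = 44))
for (m in list(supervised, ssl)) {
  r <- metrics_report(holdout$labels, predict(m, holdout$spectra))
  cat(sprintf("MAP %.1f%%  WAP %.1f%%  WR %.1f%%\n",
              100 * r$MAP, 100 * r$WAP, 100 * r$WR))
}
#> MAP 76.0%  WAP 76.0%  WR 67.5%
#> MAP 90.1%  WAP 90.1%  WR 89.5%
```

The rebalanced run lifts macro precision by 14 points; most of the gain
comes from balancing the labeled data before the loop (the step the method
treats as critical), with the high-confidence pseudo spectra adding the
rest. The five most important wavelengths of the final forest fall in the
planted informative windows:

```r
imp <- gini_importance(ssl, seed = 42)
round(default_wavelength_grid()[head(imp$top_bands, 5)], 1)
#> [1] 1663.5 1666.8 1670.1 1660.1 1567.5
```

The config-driven front end chains all stages
(simulate → screen → train → evaluate → importance) and writes metrics
JSON, an importance table and a per-iteration JSON-lines log:

```r
res <- run_pipeline(list(seed = 1), "my_run")   # or a YAML config path
res$metrics
```

A thin shell wrapper with the same stages ships in
`inst/scripts/nirssl`. See the vignette
(`vignettes/rebalanced-self-training.Rmd`) for the model, its assumptions,
what the synthetic generator does and does not emulate, and all numerical
choices.

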