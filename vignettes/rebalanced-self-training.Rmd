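---
title: "Class-rebalanced self-training for NIR leaf spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-rebalanced self-training for NIR leaf spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirssl)
```

## The problem

Diagnosing leaf nutrient status from near-infrared (NIR) reflectance is a
five-class ordinal classification problem: a leaf's nitrogen (N) or potassium
(K) concentration, measured destructively by wet chemistry, is binned into
*very low / low / proper / high / very high* by fixed agronomic breakpoints
(`class_scheme()`), and a classifier must recover the bin from the 224-band
reflectance spectrum (942–1680 nm) of the leaf. Two features of real surveys
make this hard:

* **Few labels, many pixels.** Chemistry gives one label per leaf, but a
  hyperspectral image of that leaf contains thousands of unlabeled pixel
  spectra.
* **Class imbalance.** Field populations cluster around the agronomically
  common classes; the imbalance ratio
  $\mu = C_{\max} / C_{\min}$ of the largest to smallest class count
  reaches ~10 in the data division this package emulates
  (`imbalance_ratio(split_design_counts("K")$train, counts = TRUE)`).

The package implements a semi-supervised answer: iterative **self-training**
whose per-iteration pseudo-label set is **resampled to control class
balance**, with the unlabeled pixel pool pre-filtered by a similarity screen.

## The procedure

`self_train()` runs the loop:

1. Optionally balance the labeled spectra once with SMOTE
   (`labeled_sampler = "smote"`). Doing this *before* the loop matters: a
   classifier fitted on raw skewed labels produces high-confidence
   pseudo-labels almost exclusively for majority classes, and no resampling
   scheme can recover minority information that never clears the confidence
   threshold.
2. Inject unlabeled pixels at the ratio $\beta = D_{labeled}/D_{unlabeled}$
   (`subsample_unlabeled()`; $\beta \in \{1/2, 1/4, 1/6, 1/8\}$ are the
   studied settings).
3. Iterate: fit the base classifier on labeled + current pseudo data;
   predict the injected pool; keep predictions whose maximum class
   probability reaches `tau`; resample the kept set with the chosen scheme
   (`pseudo_sampler`); record the class counts and the imbalance ratio of
   the rebalanced pseudo set. Stop when the fraction of pseudo-labels that
   changed falls below `stop_eps`, or after `max_iter` iterations.
4. Refit on labeled + final pseudo set. With `tau > 1` or `max_iter = 0`
   the result is bit-for-bit the plain supervised fit.

The four resampling schemes (`resample_set()`) differ in the per-class
selection probability: **RAS** keeps the empirical distribution
($p_j \propto C_j$), **MES** samples classes uniformly ($p = 1/k$),
**RES** inverts the frequencies ($p_j \propto 1/C_j$), and **SMOTE**
synthesizes convex combinations of minority neighbours up to the majority
count. MES and SMOTE guarantee $\mu = 1$ for the rebalanced set at every
iteration; RES drives $\mu$ down gradually through the feedback between
oversampled minorities and the next iteration's pseudo-labels; RAS tracks
the skew of the high-confidence pool.

One bookkeeping choice deserves a note: the recorded $\mu$ trajectory is
that of the *rebalanced pseudo set*, not of the union with the labeled
data. Only under that convention does the balance guarantee of MES/SMOTE
($\mu \equiv 1$) hold when the labeled data are left skewed; the labeled
set's own $\mu$ is reported separately (`mu_labeled`). Inside the loop the
MES budget is rounded down to a multiple of the number of classes present
so the guarantee is exact rather than off-by-one; the general MES remainder
rule (extra draws to the smallest classes first) still applies when
`resample_set()` is called directly.

## Similarity screening

Unlabeled pixels are screened against the labeled mean spectrum $q$ with
the scaled dot product
$\mathrm{sim}(q, k_i) = (q \cdot k_i)/d$, $d = 224$, min–max normalized to
$[0,1]$ across the pixels of a leaf (`pixel_similarity()`). This statistic
is written as a "cosine similarity" in the chemometric literature this
package follows, but it carries no vector-norm denominator and is therefore
magnitude-sensitive: brighter pixels score higher. We implement the
magnitude-sensitive form as the default because it is the screening rule
the procedure was reported with, and expose the norm-invariant cosine as
`cosine = TRUE`. Normalization is per leaf (the screening heatmap the rule
derives from is a single-leaf visualization); the keep rule defaults to the
top 30% of leaf pixels (`top_fraction = 0.3`), mirroring the observation
that the retained "vein-like" pixels are a minority of the leaf. Both the
fraction and a hard score threshold are configurable.

Before screening, spectra are smoothed with a Savitzky–Golay filter
(`sg_smooth()`, window 11 bands, polynomial order 2). At the ~3.3 nm band
spacing this window spans ~33 nm — wide enough to suppress the single-band
noise artifact near 1380 nm by well over half while reproducing polynomial
(broad absorption) features exactly.

## The base classifiers

* **PLS-DA** — PLS2 regression on one-hot class targets with an argmax
  decision, implemented in-package with the covariance-kernel algorithm
  (deflation of $X'Y$ with weight orthogonalization). Ten latent variables
  by default; the test suite cross-checks predictions against an
  independent NIPALS implementation. Per-class scores are softmax-mapped so
  every base exposes probabilities summing to one.
* **LDA** — `MASS::lda`; zero-variance bands are dropped before fitting.
* **RFC** — `randomForest`, 200 trees by default, seeded for bit
  reproducibility.

A practical note on `tau` (default 0.8): linear models emit sharp
posteriors, while forest vote fractions over five classes are conservative,
so with very small labeled sets an RFC may clear `tau` on few pixels. The
loop degrades gracefully — three consecutive empty selections return the
supervised model with a warning — and balancing the labeled data first
(step 1) raises minority-class confidence enough for the default to work in
the bundled benchmark.

## Metrics

All scores are computed from the confusion matrix only
(`summary_metrics()`): macro averaged precision
$\mathrm{MAP} = \sum_i \mathrm{Precision}^{(i)}/(k{+}1)$ over the
$k{+}1 = 5$ classes, weighted averaged precision
$\mathrm{WAP} = \sum_i \alpha_i \mathrm{Precision}^{(i)}$ and weighted
recall $\mathrm{WR} = \sum_i \alpha_i \mathrm{Recall}^{(i)}$ with
$\alpha_i = C_i / \sum_j C_j$. WR is algebraically the micro accuracy
(trace over total) — the suite fuzz-tests the identity. A class never
predicted would make precision 0/0; we define such scores as 0 and flag
them, so weighted sums stay finite and a collapsed classifier is penalized
rather than hidden. For class-fair evaluation `balance_test_set()`
downsamples every class to the smallest count ($\mu = 1$, so WAP = MAP
exactly), and `cross_validate()` reports the mean WAP over stratified
folds.

## Wavelength importance

`gini_importance()` ranks bands by total Gini-impurity decrease across all
splits of a random forest, recomputing node impurities by routing the
training spectra through each stored tree. The node index is
$G_q = \sum_{c \ne c'} p_{qc} p_{qc'}$ (equal to $1 - \sum_c p_{qc}^2$).
Two split-contribution conventions are exposed: the standard **weighted**
mode $G_q - \frac{n_i}{n_q} G_i - \frac{n_j}{n_q} G_j$ (non-negative;
default) and a **literal** unweighted difference $G_q - G_i - G_j$, which
can go negative and is provided for fidelity to the unweighted formula
sometimes printed in application papers. Profiles are normalized to sum 1.
For linear bases an auxiliary seeded forest is fitted on the same training
data. `band_element_correlation()` complements this with per-band Pearson
correlations against the measured concentrations.

## The synthetic generator

Because the original leaf data set is not redistributable, every stage is
exercised on synthetic data with the statistical structure the method
assumes (`generator_spec()`, `simulate_labeled_set()`,
`simulate_leaf_cube()`):

* a smooth NIR reflectance archetype with water-absorption dips near 1200
  and 1450 nm;
* class-conditional Gaussian bumps inside the nitrogen-informative windows
  945–980, 1548–1592 and 1651–1680 nm. Successive windows carry orthogonal
  polynomial contrasts of the five ordered levels, so class means span
  several spectral directions; a single shared contrast would make the
  means collinear, which artificially masks the middle classes for linear
  one-hot classifiers and collapses the outer class pairs onto each other;
* per-sample multiplicative scatter ($1 + \varepsilon$,
  $\varepsilon \sim N(0, 0.02)$), additive band noise
  ($\sigma = 0.012$ reflectance units), and a high-variance single-band
  spike at 1380 nm ($10\sigma$) that the Savitzky–Golay filter must
  demonstrably suppress;
* concentrations drawn uniformly within each class's breakpoint interval;
  the open-ended outer classes use a bounded extension of the neighbouring
  interval's width, since the regulations give no outer bounds;
* leaf cubes: an elliptical leaf mask, a midrib-plus-laterals vein mask,
  vein pixels tracking the leaf mean closely (gain 1.04, low noise), lamina
  pixels slightly attenuated with stronger noise and a spatially correlated
  scatter field (separable moving average — cheap, and sufficient to make
  pixel screening non-trivial). The two gains are tied so the leaf-mask
  mean converges to the generating class mean. The small vein/lamina
  brightness asymmetry is what makes the magnitude-sensitive screening
  statistic rank vein pixels first, reproducing the observed structure; it
  is deliberately kept at a few percent so screened pixels remain
  exchangeable with labeled mean spectra instead of forming a shifted
  domain.

The default class-count profile is the nitrogen training division
45:93:225:104:268 ($\mu \approx 5.96$). The default `effect_size = 0.8`
(adjacent-class separation in noise-SD units at the window centers) was
calibrated once so that a supervised random forest on the full default
set lands mid-range on a balanced test set (~0.7 WAP, the regime of
interest for the method) rather than at ceiling or chance; tests that
study stronger signals pass `effect_size` explicitly. Generation is a pure
function of the spec including its seed.

What the generator does **not** emulate: biophysical leaf optics
(no radiative-transfer model), instrument drift, water-band nonlinearity,
spatially varying illumination, or label noise in the chemistry. Passing
tests on this generator therefore show that the pipeline's machinery is
correct and that its balance/benefit properties hold under the assumed
statistical structure — not that the reported real-data scores transfer.

## Numerical and design choices

* `tau = 0.8`, `max_iter = 10`, `stop_eps = 0.01` by default; all exposed.
  Pseudo-budget per iteration is one labeled-set-worth, capped by the
  high-confidence count.
* Pseudo data are re-selected from the full injected pool each iteration
  (transductive restyle) rather than consumed destructively; this is what
  lets per-iteration class histograms grow and rebalance.
* `beta` counts the injected pool before confidence filtering; a pool
  smaller than the quota is used whole with a warning.
* Min–max normalization of a constant vector returns zeros with a warning.
* Ties in argmax decisions go to the lowest class index; screening ties
  break by pixel raster order; all samplers shuffle output by their seed.
* SMOTE uses Euclidean distance on the (smoothed) spectra, `k = 5`
  neighbours, reduced with a warning for tiny classes; a single-sample
  class falls back to duplication.
* Pairing SMOTE labeled balancing with the RES pseudo-sampler triggers a
  validation warning: reverse sampling is designed to start from the raw
  skewed labels.
* ENVI I/O is float32 with BIL/BIP/BSQ interleaves; masks travel as 0/1
  text sidecars. The raw instrument grid (256 bands, 866–1701 nm) and the
  trimmed working grid (224 bands, 942–1680 nm) are both exposed; the two
  are arithmetically inconsistent in the source material (dropping 32 bands
  from the former does not yield the latter), and the trimmed grid is
  treated as authoritative for all downstream types.

## Problem sizes used by the test and acceptance suites

The bundled suites run entirely on synthetic data at desk scale: labeled
sets of 50–750 samples, single leaves up to 64×64 pixels, forests of
100–200 trees, 10-seed paired benchmarks and 20-seed recovery runs. These
sizes were chosen as the smallest at which the studied contrasts (SSL vs
supervised ordering, balance guarantees, planted-window recovery) are
stable across seeds.

## Known limitations

* PLS-DA probabilities are a softmax convenience, not calibrated
  posteriors; confidence thresholding with PLS-DA is therefore coarser
  than with LDA.
* Gini importance inherits the known bias of impurity-based rankings
  toward high-variance features; the 1380 nm artifact band is deliberately
  left in the generator so users can observe this when smoothing is
  skipped.
* The RES trajectory's approach to $\mu = 1$ is emergent, not guaranteed;
  with a degenerate base classifier it can stall.
* `cross_validate()` refolds only by stratified assignment; with classes
  smaller than the fold count a fold can still lose a class (it then scores
  with flagged zero precisions).
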