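---
title: "Transferring feature-stability information by data augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferring feature-stability information by data augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative feature tables extracted from medical images (radiomics
signatures) are sensitive to acquisition and annotation factors that have
nothing to do with the clinical prediction target: scanner and
reconstruction settings, rater differences in delineation, imaging
parameters. Such a factor is a *confounding variable* $v$: each feature
value is really $x_{i,j}(v)$, and a model trained at one value of $v$ may be
evaluated, in deployment, at another.

Because rescanning or re-annotating a whole cohort is rarely feasible,
practice is to run a small *side study* — scan-rescan or
annotate-reannotate on a handful of subjects, or a phantom experiment —
that measures the same subjects under two confounder values. The side study
carries information about feature stability but (typically) none about the
prediction target. The question this package addresses: **what is the best
way to carry the side-study information into the main modelling study?**

Four strategies are implemented and benchmarked:

* **simple** — ignore the side study. The baseline everyone uses implicitly.
* **filtering** — the current standard: drop features that are unstable in
  the side study, using Lin's concordance correlation coefficient (CCC, for
  paired side studies, threshold $\tau_{CCC} = 0.8$) or an uncorrected
  two-sample t-test (unpaired, removal below $\tau_{test} = 0.05$).
* **proposed** — data augmentation for information transfer (DAFIT):
  estimate a per-feature noise model from the side study and add that noise
  to the main-study observations, so target-aware, embedded feature
  selection can trade stability against information content on its own.
* **combined** — filter first, then augment the surviving features.

An **oracle** reference trains on data that itself contains the confounder
variation; it bounds what any correction could achieve but is not available
in a real study.

## The noise model and the augmentation transform

The confounder effect on a feature is modelled as additive Gaussian noise.
The transform applied to a main-study observation $x$ is

$$\Theta(x \mid \mu, \sigma^2) = x + \mathcal{N}(\mu, \sigma^2),$$

drawn independently per feature and per augmented copy. Per feature,
$(\mu_j, \sigma_j^2)$ is estimated from the side study:

* **paired**: mean and sample variance of the within-pair differences
  $b_{ij} - a_{ij}$ — the difference of two measurements of the same
  subject is attributed entirely to the confounder;
* **unpaired**: difference of the group means, and the *sum* of the two
  group sample variances (Bienaymé formula for the variance of a
  difference of independent variables). This necessarily includes the
  biological within-group variance, so the unpaired estimator is inflated;
  this is a property of the design, not of the implementation.

Two augmented copies per original observation are generated by default, and
they *replace* the originals (`include_originals = FALSE`); keeping the
originals as well is exposed as an option since either reading of
"augmented observations were used" is defensible.

Choices worth making explicit:

* **Variance divisor.** Sample variance ($1/(m-1)$) in both estimators:
  side studies are small, and the unbiased divisor matters at $m = 20$–$30$.
* **Sign of $\mu$.** The convention is $b - a$: augmentation pushes the
  main study *toward* measurement condition b. When the correspondence
  between side-study groups and the main study's acquisition condition is
  unknown, `symmetrize_noise()` zeroes $\mu$ and transfers only the
  variance; both behaviours are exposed because the direction is genuinely
  ambiguous in most real side studies.
* **Where augmentation happens.** Inside each cross-validation training
  fold only, never on held-out rows. Augmenting before the fold split would
  place perturbed copies of a held-out subject into the training part and
  leak. (Augmenting once per dataset would be cheaper; the per-fold choice
  is the conservative one.)
* **Normality.** The Gaussian form is an assumption, not a fact; the
  Shapiro–Wilk diagnostic (`normality_diagnostic()`, Bonferroni-corrected
  across features) reports how many features are consistent with it. The
  skew-normal option of the generator exists to probe how much a violation
  hurts.

## Stability filters

`ccc_filter()` implements Lin's estimator with population ($1/n$) moments,

$$CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

keeping features with $CCC \ge \tau_{CCC}$ (default 0.8, the threshold in
common radiomics use; it is a parameter, not a recommendation).
`ttest_filter()` removes features whose two-sided p-value falls below
$\tau_{test}$ (default 0.05) with **no** multiple-testing correction — the
filter's semantics are a probability threshold, so under a true null it
removes about 5% of features by construction; the Welch variant is the
default because confounder groups carry no equal-variance guarantee
(`var_equal = TRUE` restores the pooled test).

Degenerate columns are handled deterministically rather than propagating
`NaN`: two identical constant vectors are in perfect agreement
(CCC 1, p 1, kept); constant but unequal vectors are in maximal
disagreement (CCC 0, p 0, removed).

## The synthetic benchmark

`generate_benchmark()` builds a self-contained test bed with known ground
truth, emulating a typical radiomics study size:

| parameter | default | meaning |
|---|---|---|
| `n_features` | 4000 | features per observation |
| `n_informative` | 20 | features whose class means differ |
| `n_train_per_class` | 150 | training cohort per class (no shift) |
| `n_test_per_class` | 500 | test cohort per class (shifted) |
| `feature_mean_range` | [-1, 1] | uniform range of per-feature base means |
| `feature_sd_range` | [0.5, 2] | uniform range of per-feature base sds |
| `effect_size` | 1.0 | class-1 mean shift, in units of the feature's sd |
| `shift_mu_sd` | 1.0 | sd of the systematic per-feature confounder shift |
| `shift_sigma_range` | [0, 1] | per-feature sd range of per-observation shift noise |

The test set's confounder shift has a per-feature *systematic* component
$\delta_j$ (drawn once, constant across test observations — "the scanner
changed") plus per-observation noise of per-feature sd $\sigma_j$. The
side study (`generate_side_study()`) draws subjects from the class-0
distribution only — a stability experiment knows nothing about the target —
and applies exactly the same shift model to the second measurement, so a
noise model estimated from it recovers the generating truth up to sampling
error.

The hyper-distribution values (mean/sd ranges, effect size, shift scales)
are this package's choices and are all exposed in `benchmark_config()`.
The *qualitative* strategy ordering reported below is stable across scales;
exact counts (how many features a filter keeps, how many informative
features survive) are not, and no such count should be compared across
generators with different hyperparameters.

What the generator deliberately does **not** emulate: correlation structure
between features (real radiomics features are heavily correlated),
heavy-tailed marginals, multi-rater geometry, or confounder effects that
interact with the class. Passing benchmarks here therefore show that the
machinery behaves as designed under its own model — not that the gains
carry to any particular real dataset, where the value of augmentation
depends on how well the side study's noise describes the main study's.

## The evaluation protocol

`run_strategy()` measures two things per strategy × classifier:

* **model performance** — AUC (Mann–Whitney, ties one half) of the final
  model on each confounder-shifted test group, refit on the whole processed
  training pool;
* **honesty of the performance estimate** — the absolute estimation error
  $$AEE = \lvert AUC_{CV} - \min_g AUC_{C_g} \rvert,$$
  the gap between the five-fold cross-validated estimate and the *worst*
  left-out-group performance. A large AEE means the study would have
  reported a number its deployed model cannot deliver.

Protocol details: outer 5-fold stratified CV; the strategy (filter /
augment / SMOTE) is applied to the fold-training rows only; hyperparameters
are tuned by inner 3-fold stratified CV within each outer training part;
held-out rows are scored untouched. Learners: random forests (ranger),
gradient boosting (xgboost) and L1-penalized logistic regression (glmnet,
which standardizes internally from training rows only — the tree learners
see raw features). Default tuning grids are small and documented in
`default_tuning_grid()`; a single-row grid skips the inner loop, which is
how the heavy benchmark runs keep nested tuning affordable. All
randomness — fold assignment, augmentation draws, forest seeds — derives
from one explicit seed, so every result is exactly reproducible.

The SMOTE control (`smote = TRUE` on any strategy) oversamples the
processed training rows by convex interpolation between same-class nearest
neighbours until the row count matches what DAFIT augmentation would have
produced. It adds rows but no confounder information, separating the
sample-size effect from the information-transfer effect.

A strategy that fails — e.g. a filter that removes every feature — becomes
a flagged failed row in `run_experiment()`'s table rather than an
exception, so sweeps over many configurations keep running.

## What the benchmark shows

At the reduced scale used in the tests and the acceptance script (1000
features, 20 informative, 150/class training, 500/class shifted test, 10
repeats, RF + GBM fused; about 40 s per repeat on one core):

* the **simple** strategy's CV estimate overshoots its shifted-test
  performance (largest AEE of the three applicable strategies);
* **filtering** shrinks the AEE but pays for it in model performance, since
  informative-but-unstable features are gone;
* **proposed** attains both the smallest AEE and the highest shifted-test
  AUC of the three, and SMOTE-matching the filtering strategy's sample
  count does not close the gap — the benefit comes from the transferred
  noise information, not from the extra rows.

These are the quantities `scripts/acceptance.R` recomputes end to end; the
test suite asserts the ordering, not the exact values, which move with the
generator's hyperparameters.

## Numerical conventions and limitations

* Missing feature values are an error everywhere; no imputation.
* Binary class labels only; multi-class problems are out of scope.
* Tie-breaks: inner-CV tuning picks the first grid row on ties; SMOTE
  neighbour ties are broken by row index.
* The noise model is per-feature independent; correlated confounder
  effects (and batch-correction methods that model them) are outside the
  current model.
* Side studies with more than two repeated measurements per subject are
  not modelled; reduce them to two groups before constructing the
  `side_study`.
* AUC confidence intervals in experiment summaries are percentile
  bootstraps of the mean across repeats (2000 resamples), which slightly
  undercover at 10 repeats; they are descriptive error bars, not tests.
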