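---
title: "Methods: multicenter radiomics preprocessing and the evaluation grid"
author: "radgrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multicenter radiomics preprocessing and the evaluation grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radgrid)
```

## The problem

Radiomic features extracted from PET/CT images of breast tumors can carry
signal about whether the axillary lymph nodes will show a pathological
complete response (pCR) after neoadjuvant chemotherapy. Two nuisances stand
between that signal and a model that transfers across hospitals:

* **patient-level uptake variation** — SUV-derived PET features share a
  global per-patient multiplicative factor (blood glucose, tracer clearance,
  post-injection timing), and
* **scanner batch effects** — per-feature location and scale differences
  tied to the scanner, not the biology.

`radgrid` implements a preprocessing-and-evaluation pipeline for exactly this
setting: tumor-to-liver ratio (TLR) features to cancel the uptake factor,
ComBat or Limma-style harmonization to remove scanner effects,
post-extraction feature discretization for robustness, and a factorial grid
of 630 modelling configurations evaluated by repeated balanced down-sampled
splits. Because no patient data ship with the package, a synthetic cohort
generator with known ground truth stands in for the data; every stage is
tested against that truth.

## Pipeline stages

### Reproducibility and redundancy filtering

Three segmentation replicates (two readers, one reading twice) give three
replicate pairs. For each feature, `icc_filter()` computes ICC(2,1) —
two-way random effects, absolute agreement, single rater, the standard form
for radiomics test–retest studies — for every pair, and retains a feature
only when **all three** pairwise ICCs exceed the threshold (default 0.75).
The all-pairwise rule is the conservative reading of testing "between every
two groups"; the ICC form itself is a design choice, since several variants
exist. Features whose ICC is undefined (zero variance) are dropped with a
warning.

`correlation_prune()` then removes redundant features: visiting features in
column order, a feature is dropped when its absolute Pearson correlation
with any already-kept feature exceeds 0.9. Greedy column-order pruning is
order-dependent; we prefer a deterministic, reproducible rule over an
optimal one. |r| rather than signed r is used, so an anti-correlated copy
of a kept feature is also pruned. Constant features (undefined correlation)
are treated as correlation 0 and never pruned for redundancy.

Both filters run once on the full dataset before the grid, matching the
workflow they reproduce; a leakage-safe variant of the downstream
preprocessing is available (see *Leakage semantics*).

### OR and TLR feature sets

`assemble_or()` passes CT + PET tumor features through unchanged ("origin
radiomics"). `assemble_tlr()` divides each PET **intensity** tumor feature
elementwise by its same-named liver counterpart; PET shape/volume features
and CT features pass through. Shape features are geometric, carry no uptake
factor, and are therefore excluded from the ratio. A liver denominator
smaller than `1e-12` in magnitude excludes that feature entirely rather than
producing an unstable ratio.

If tumor and liver values share a multiplicative factor `u` (the patient's
uptake), the ratio cancels it exactly in the noise-free limit; with additive
residual noise the cancellation is approximate, which is why the synthetic
tests check exactness only at `noise_sd = 0`.

### Harmonization

Two methods, implemented natively over the same interface:

* `combat_fit_transform()` — parametric empirical-Bayes ComBat: per-feature
  standardization by grand mean and pooled SD; per-(batch, feature) location
  (`gamma`) and scale (`delta`) estimates shrunk toward method-of-moments
  hyperpriors (normal for location, inverse-gamma for scale) by iterated
  conditional posterior means; adjustment and back-transformation. The
  iteration stops at a relative change below `1e-4` (cap 100 iterations),
  the conventional ComBat stopping rule. Features constant within any batch
  cannot be standardized and pass through unadjusted, with a message. When
  fewer than two features are adjustable the hyperpriors are not estimable
  and the unshrunken estimates are used.
* `limma_fit_transform()` — per feature, ordinary least squares on batch
  indicators; the centered batch component is subtracted, equalizing batch
  means exactly while preserving the overall feature mean exactly.

No biological covariates are protected by default (the workflow being
reproduced does not state protecting any); a `protect` argument accepts
`sample_meta` columns whose linear effects are preserved during
standardization. Both fitted models can be applied to new samples from seen
batches via `apply_harmonization()` without re-estimation.

### Discretization

Feature values (not image voxels) are discretized to integer bins `1..n` by

* **FBN** (fixed bin number, equal frequency):
  `y = ceil(n * (Rank(A(x)) - 1) / (Counta(A) - 1))`, `y = 1` at the
  minimum; ranks are ascending competition ranks, so tied values share the
  smallest ordinal and can never straddle a bin boundary (the tie rule is a
  design choice — average ranks would put ties on boundaries);
* **FBW** (fixed bin width, equal range):
  `y = ceil(n * (A(x) - min(A)) / (max(A) - min(A)))`, `y = 1` at the
  minimum; a constant feature maps wholly to bin 1 by extension of the
  minimum rule.

A tolerance of `1e-12` is subtracted before the ceiling so that a float ulp
at a mathematically exact bin edge cannot promote a value to the next bin;
the tests verify agreement with an exact-rational-arithmetic oracle.
`discretize_apply()` bins held-out samples with the frozen training state:
FBW clips into `[1, n]` with the stored min/max; FBN ranks a new value as
the competition rank of the largest training value not exceeding it.

### The evaluation grid

`enumerate_grid()` is the full factorial: feature type (OR, TLR) x batch
method (none, ComBat, Limma) x discretization (none, FBN32, FBN64, FBW32,
FBW64) x selector (DT, RF, XGB) x classifier (DT, ET, KNN, RF, SVM, XGB,
SGD) — 630 configurations; the factorial marginals are 315 per feature
type, 210 per batch method, 126 per discretization, 210 per selector and 90
per classifier. (A published description of this grid gives 320 per feature
type, which is arithmetically inconsistent with a 630-cell two-level
factor; the factorial value 315 is implemented.)

Per configuration, `evaluate_config()` repeats: balanced down-sampling of
the majority outcome class of the source scanners to the minority count, a
stratified 80/20 train/validation split (`floor(0.8 * n)` per class to
train), top-10 feature selection on the training set by the configuration's
tree-based importance, classifier training, and AUC on the validation set
and on the held-out test scanner. Validation and test AUCs are averaged
over repeats and their mean ranks the configuration. The same repeat seeds
drive every configuration, so comparisons between configurations are
paired. Classifier and selector hyperparameters are library defaults at
desk scale (200 trees for the forests, 50 boosting rounds with depth-3
trees, k = 5 neighbours, radial SVM); the SGD classifier is logistic
regression fitted by stochastic gradient descent on the log loss so that a
probability score exists for the AUC; the SVM contributes orientation-
corrected decision values, which are rank-equivalent to probabilities for
AUC purposes. All fits are single-threaded and seeded.

Repeats default to 100 (the workflow being reproduced used 1000); the
bundled analysis scripts and acceptance checks use 50 repeats on cohorts of
150–300 samples with 200 features, which keeps a full pass through the test
suite and the acceptance script within a few minutes on one core while
leaving the Monte-Carlo error of a 50-repeat mean AUC near 0.005.

### Leakage semantics

The default mode fits harmonization and discretization on all samples
(including the test scanner) before splitting — matching the workflow being
reproduced, which preprocessed before model building. This is deliberate
fidelity, not an endorsement: it lets information about the test batch's
location and scale (not its labels) into preprocessing. A `train_only` mode
fits both on the source scanners and applies the frozen models to the test
batch; since the test scanner is by construction a batch never seen at
harmonization time, its features are then left on their own scale rather
than adjusted by another batch's estimates. Feature selection and
classifier training are always strictly train-only in both modes.

## The synthetic cohort generator

`simulate_cohort()` draws, per feature, a positive base level (log-normal
across features, constant across samples) and generates

```
value = (base + effect * informative * pCR + batch_shift)
        * batch_scale * uptake^[PET intensity] + noise
```

with `batch_shift ~ N(0, batch_shift_sd * base)` per (batch, feature),
`batch_scale = exp(N(0, batch_scale_sd))`, a per-patient
`uptake = exp(N(0, uptake_sd))` shared by all PET intensity tumor and liver
features, and residual `noise ~ N(0, noise_sd * base)`. Because all
within-batch, within-class variation comes from the noise term, switching
every noise source off makes samples identical — a property the tests use.
The class effect is `effect_size` in units of the within-class SD, so the
standardized mean difference on each informative feature equals
`effect_size` on the clean scale.

Choices worth flagging:

* **Informative features sit on PET intensity features** (spilling into CT
  only if more are requested than exist): the premise of uptake
  normalization is that the discriminative metabolic signal rides on PET
  uptake features. This is what makes the TLR-versus-OR contrast
  structural: the uptake factor corrupts exactly the informative features
  under OR.
* **Liver noise is `liver_noise_frac` (default 0.2) of tumor noise**: the
  liver VOI is a large homogeneous normal-tissue region, far less variable
  than a tumor segmentation.
* **Clinical covariates** ER/PR/HER2 are Bernoulli(1/2) with a logistic
  link to pCR (default odds ratios 2.5/2/2, intercept solved so the
  marginal prevalence hits `pcr_prevalence` = 0.35, the 52/147 figure of
  the motivating cohort); effect sizes are chosen to make chi-square tests
  informative around n = 150, since only the direction ("meaningful") is
  reported in the source setting.
* **Replicates** are the tumor table plus independent additive Gaussian
  perturbations (`replicate_noise_sd`, default 0.2·base); 10% of features
  get a 10x inflated replicate noise so the ICC filter has a planted target.
  No model of reader-specific bias is attempted.
* Default nuisance magnitudes — `batch_shift_sd = 0.5`,
  `batch_scale_sd = 0.2`, `uptake_sd = 0.3`, `noise_sd = 0.5` — are
  plausible for multicenter SUV-derived features, not fitted to any dataset:
  inter-scanner effect magnitudes are simply not characterized in the
  setting being emulated.

`bayes_auc()` gives the recovery ceiling: the Monte-Carlo AUC (1e5 draws
per class) of the oracle linear score `sum(effect_j * x_j / var_j)` over the
informative features on the clean signal scale. For one informative feature
with standardized effect `d` it converges to `pnorm(d / sqrt(2))`; for the
default design (20 features, d = 0.8) it is about 0.994.

What the generator does **not** emulate: feature-family correlation
structure (real radiomic features are heavily clustered; here features are
conditionally independent, so redundancy pruning has little to do),
non-Gaussian heavy tails, reader-specific segmentation bias, missing data,
and any image-level physics. Passing tests therefore demonstrate that the
pipeline recovers planted structure of this statistical shape — not that it
would perform identically on real multicenter images.

A note on recovery: the clean-signal oracle uses all informative features
at their undiluted effect size, while the pipeline sees features after
uptake heteroscedasticity (noise enters after the multiplicative factors,
so low-uptake patients carry proportionally more noise), batch-scale
spread, and the liver ratio — and keeps only the top 10. Under the default
nuisance magnitudes the best configuration therefore lands several AUC
points below the oracle. The acceptance script reports both the oracle and
the best configuration's test AUC so the gap is visible rather than hidden.

## Inference machinery

* `auc()` — Mann–Whitney estimator with tie handling, checked against
  exhaustive pair counting.
* `delong_test()` — the fast structural-components (midrank placement)
  algorithm for two correlated AUCs; two-sided normal p primary, both
  one-sided ps also reported (published comparisons in this setting appear
  to report the one-sided lower tail without saying so). A zero estimated
  variance of the difference (e.g. identical score vectors) is flagged
  degenerate and reported as `z = 0, p = 1` rather than dividing by zero.
* `permutation_test()` — B label permutations (default 999) with the
  add-one correction `p = (1 + #{null >= Sobs}) / (B + 1)`, which can never
  return 0.
* `compare_auc_groups()` — per-level mean AUC with a 95% **percentile**
  interval of the per-configuration AUC distribution (the interval widths
  published for such comparisons are far too wide to be standard errors of
  a mean over hundreds of configurations, so the percentile reading is
  used), plus pairwise Welch and Mann–Whitney p-values; Mann–Whitney is
  primary because mean-AUC distributions are bounded and skewed. No
  multiple-testing correction is applied across these comparisons, matching
  the workflow being reproduced.
* `clinical_tests()` — chi-square for categorical covariates against
  outcome with a Fisher fallback when any expected cell is below 5; Welch t
  for continuous ones.

## Radiomics score and nomogram

`radiomics_score()` is the plain weighted sum `sum(F_i * W_i)` over the ten
selected features, with the selector's importance scores as weights — not
refitted regression coefficients; the score is deliberately the one the
selector implies. `fit_combined_model()` is maximum-likelihood logistic
regression of pCR on the r-score and ER/PR/HER2 (coded 0/1), with
separation detection. `export_nomogram()` maps each predictor to a points
axis — reference value at the low-linear-predictor end of its observed
range, points accruing at `scale * coefficient` per unit, scale chosen so
the largest absolute effect spans exactly 100 points — and the total-points
axis back to probability through the inverse logit of the affine
back-transform. The mapping is exact by construction: the round trip from
points to probability reproduces the logistic model's fitted probabilities
to numerical precision, which the tests assert at `1e-9`. Zero-range or
collinear (NA-coefficient) predictors carry no points and are excluded with
a warning; an intercept-only model degenerates to a constant-probability
nomogram.

## Known limitations

* The default preprocessing mode is deliberately not leakage-safe across
  the test scanner (see *Leakage semantics*).
* Non-parametric ComBat, reference-batch ComBat and longitudinal variants
  are out of scope; so are hyperparameter tuning and nested
  cross-validation inside the grid.
* The greedy correlation pruner guarantees no kept pair exceeds the cut but
  not a maximal kept set.
* KNN's vote-sharing probabilities are coarse (k = 5), which discretizes
  its AUC on small validation sets.
* The permutation test permutes outcome labels only; it does not re-run
  ICC filtering or pruning, which are outcome-blind.
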