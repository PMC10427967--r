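---
title: "Consensus metabolite modeling of MSC potency: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus metabolite modeling of MSC potency: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mesenchymal stromal cells (MSCs) are manufactured cell therapies whose
immunomodulatory potency varies strongly between donor lines and
manufacturing runs. A practical release assay needs *critical quality
attributes* (CQAs): measurable quantities, ideally available in-process,
that predict the functional potency of the finished product. `mscpotency`
implements a consensus machine-learning framework for discovering candidate
metabolite CQAs from two kinds of data collected during MSC expansion:

* **end-of-process intracellular metabolomics** — untargeted LC-MS feature
  tables (lipids and small polar metabolites) from harvested cell pellets;
* **in-process media metabolomics** — NMR spectral features of conditioned
  medium sampled daily over the first three culture days.

Because any single regression family carries its own inductive bias, the
framework fits *seven* families and keeps only features that at least two
of them rank as important. The surviving "consensus panel" is then refit in
every family and evaluated by leave-one-out R², so the final claim — *this
panel predicts potency* — does not hinge on one model class.

# The potency response

Each MSC line is phenotyped with five functional assay variables: CD4⁺ and
CD8⁺ T-cell proliferation (%CFSE dilution under MSC co-culture) for two
independent PBMC donors, and IDO activity in pg L-kynurenine per cell per
day (`ido_activity_per_cell()` performs the per-cell, per-day
normalization). `composite_score()` autoscales the five variables across
lines and takes each line's first-principal-component coordinate as its
composite potency score.

Two choices deserve comment:

* **Autoscaling before PCA.** The assay variables live on wildly different
  scales (percent vs pg/cell/day); unscaled PCA would simply recover the
  IDO axis. Autoscaling makes the score a balanced summary, and makes it
  invariant to affine rescaling of any single assay column (tested).
* **Sign orientation.** A principal component is defined up to sign. The
  PC1 sign is fixed so that the loading-weighted mean over the four
  proliferation variables is positive; higher proliferation (weaker
  suppression) then always maps to a *higher* score, i.e. the most potent
  lines have the *lowest* scores. This rule is deterministic and
  data-independent.

# Preprocessing

The MS chain is `blank_qc_filter()` → `rsd_filter()` →
`median_normalize()` → `combat_correct()` → `autoscale()`, with the
defaults of the untargeted-metabolomics workflow it mirrors: a feature is
kept when its mean experimental signal is at least **5×** its mean blank
signal and it is nonzero in at least **50%** of pooled-QC injections; the
relative-SD filter threshold is **25%**. Two points are deliberate:

* **RSD filter direction.** The default removes features with RSD *below*
  25% — i.e. near-constant features that cannot carry a cross-line signal.
  This is the literal reading of the workflow being reproduced;
  `mode = "remove_above"` provides the conventional QC-repeatability
  reading. Both are exposed because published pipelines are ambiguous on
  this point.
* **Blank rule statistic.** The 5× rule compares *means* (not maxima) of
  experimental vs blank signal; means are the stabler statistic at a
  handful of blanks.
* **Zeros and missing values.** Missing abundances are rejected at the raw
  stage rather than imputed; zero intensities flow untouched into the
  filters (the QC-presence rule is the mechanism that removes
  dropout-ridden features). No log transform is applied anywhere — the
  modeling operates on median-normalized, autoscaled peak areas.

Batch correction uses the parametric empirical-Bayes ComBat model (via the
sva package): per-batch, per-feature location and scale effects are shrunk
toward batch-level hyperpriors and removed. A single-batch table is a fixed
point; features with zero within-batch variance are left uncorrected with a
warning rather than crashing the run. The MS pipeline order
(filter → normalize → ComBat → autoscale) is configurable because published
descriptions do not fix the position of batch correction relative to
normalization.

The NMR chain batch-corrects the raw feature table, then forms
**day-difference features**: for each culture flask, `day_difference()`
subtracts the day-1 value from the day-2 or day-3 value, so a feature's
value becomes its net change over the interval. This avoids assuming
linear or even monotonic dynamics of media metabolites — the generator
plants saturating and non-monotonic trajectories precisely so tests
exercise that case. Replicate flasks are averaged per line before
regression; the flask-resolution difference table is retained for audit
(the two aggregation orders commute on balanced designs, and a test pins
that).

`variance_filter_select()` reduces the differenced feature set before
modeling: for each candidate fraction in a grid (default 5%…100% in 5%
steps), it keeps the top fraction of features by cross-line variance, fits
a PLS regression of the potency score on them, and scores the subset by
pooled leave-one-out R². The leave-one-out criterion, rather than training
R², is what prevents the filter from trivially choosing the full set.
Ties resolve toward the smaller fraction. The PLS component count inside
the filter is `min(2, n_lines − 2)` — appropriate for the ten-line regime.

# The model suite

Six standard regression families (`fit_suite()`): PLSR, linear SVR, random
forest, gradient boosted regression, decision tree, and the LASSO — backed
by mixOmics, e1071, randomForest, xgboost, rpart and glmnet respectively.
Each family runs the same protocol (`fit_model()`):

1. **Grid-search tuning** with 5-fold cross-validation scored by R², folds
   from a seeded shuffle, ties to the first grid point. Default grids:
   LASSO λ ∈ 7 log-spaced points in [10⁻³, 10]; PLSR components 1–4;
   SVR cost ∈ {0.1, 1, 10} × ε ∈ {0.01, 0.1}; RF/GBR trees ∈ {100, 500} ×
   depth ∈ {2, 3, unrestricted}; DT depth ∈ {2, 3, 5, unrestricted}.
2. **Same-family feature selection**: the tuned family is fit on all
   features and keeps those its own importance measure supports — nonzero
   coefficients (LASSO), nonzero impurity importance (RF/GBR/DT),
   VIP ≥ 1 (PLSR), or the smallest prefix of |standardized coefficient|
   mass reaching 50% (linear SVR). Selection is one thresholding pass plus
   refit, not recursive elimination — the simplest protocol that is stable
   at ten samples. An empty selection falls back to the full set with a
   message.
3. **Re-tuning on the selected subset** (on by default, configurable).
4. **Importance extraction**, normalized to sum to one: |standardized
   coefficients| for LASSO/SVR, VIP for PLSR, impurity importance for the
   tree families.
5. **Leave-one-out R²**: each line is held out in turn, the model is refit
   with *fixed* hyperparameters and *fixed* feature subset, and
   R² = 1 − Σ(yᵢ−ŷᵢ)²/Σ(yᵢ−ȳ)² is pooled over the held-out predictions.
   Because hyperparameters and the subset are chosen on the full data,
   this estimate shares the optimistic bias of the protocol it reproduces;
   it is a model-comparison statistic here, not an unbiased generalization
   estimate.

# Symbolic regression

`sr_fit()` is a genetic-programming engine over expression trees with
operators {+, −, ×, protected ÷, square}, feature leaves and constant
leaves. Protected division floors the denominator magnitude at 10⁻⁶
(preserving sign), so every expression evaluates finitely. Fitness is
training R² minus a parsimony penalty of 10⁻³ per node; evolution uses
ramped grow/full initialization, tournament selection (size 3), subtree
crossover and mutation, one-elite survival, and an offspring node-count
ceiling of 64. Each of the (default 30) restarts archives its best
expression per complexity level, and a restart stops early once an
expression reaches R² = 0.999.

**Complexity** is the expression's node count. The qualifying set for
variable-presence statistics is every archived expression with training
R² ≥ 90% and complexity ≤ 300; `variable_presence()` reports, per feature,
the fraction of qualifying models containing it, and features at presence
≥ 10% (inclusive) form the SR family's important set. The 300 ceiling is
generous for node-count trees — the R² threshold does the real work — but
is kept as the interface default so users of complexity-heavy engines can
tighten it meaningfully.

For consensus-model evaluation, the best qualifying expression's
*structure* is frozen and only its linear coefficients are re-estimated per
leave-one-out fold, by least squares on the basis spanned by the tree's
top-level additive terms (`sr_loo_r2()`). This mirrors the fixed-structure
LOO protocol of the other families without re-evolving per fold.

# Consensus, refit, ablation

`top_fraction_features()` takes each standard family's top
⌈fraction × m⌉ features by normalized importance (m = features in that
family's final model; ties break by stable input order); the SR family
contributes its presence-rule set instead. A family whose final importances
are degenerate (all-zero raw importance, e.g. a LASSO that kept the full
set only via the empty-selection fallback) found no signal and contributes
an *empty* set — letting it vote a uniform top-k would inject arbitrary
features into the panel.

`build_consensus()` keeps features flagged by at least `min_models = 2`
families, retaining the per-feature membership map. The default
`top_fraction` is 0.20; 0.10 is equally defensible (both appear in the
literature this reproduces) and is a single-argument change. Lowering
`min_models` or raising `top_fraction` can only grow the panel (tested
monotonicity).

`consensus_refit()` re-tunes and re-evaluates every family on the
panel-restricted matrix without re-selection — the panel *is* the feature
set. MS lipid and small-polar panels are built separately and unioned for a
combined consensus model; the two NMR timepoint datasets are
consensus-scored independently and features consensual in both are
flagged. `ablation_refit()` drops a user-named line (designed for the
study's induced-pluripotent-derived outlier line), re-tunes with 3-fold CV
to suit nine samples, and re-evaluates the *same* panel, quantifying how
much the consensus models lean on a single atypical line.

# Enrichment

`ora()` is a plain hypergeometric over-representation test of a mapped
query set against user-supplied GMT pathway sets, with a Benjamini-Hochberg
q-value across pathways. The background universe defaults to the union of
the supplied sets and should normally be overridden with the annotated
feature universe of the experiment; no pathway content ships with the
package. Printed p-values of specific database services are not
reproducible offline and are not targets.

# The synthetic-study generator

`generate_study()` emulates the statistical structure the analysis
assumes, so every downstream stage is testable without any download:

* One **latent potency factor** per line (standard normal) drives
  everything — the simplest generative model consistent with the claim
  that both media and cellular metabolites predict a PC1 potency score.
* The **assay panel** is a noisy affine transform of it: proliferation
  variables decrease with potency (slopes 8–11 points per latent SD, noise
  SD 3 points — proliferation readouts of the two PBMC donors are then
  correlated near 0.9, as in real panels), IDO increases with potency but
  carries 3× the noise, reproducing the observed phenomenon of mid-range
  IDO in a line with extreme T-cell readouts.
* **Features** are log-normal: log-intensity = baseline + β·latent +
  noise, exponentiated so raw tables are positive. The informative-feature
  slope is `effect_size × replicate_noise_sd` per latent SD — "effect size
  in feature-SD units". The default replicate noise of 0.2 log-units
  (≈20% CV) is typical replicate variation for untargeted MS; at that
  noise an effect size of 3 SD is a genuinely strong planted signal, which
  is what the recovery tests assume. (At substantially larger log-noise
  the exponentiation makes raw-scale associations markedly sub-linear and
  "3 SD" stops being strong — a property of log-normal data worth
  remembering when interpreting effect sizes.)
* **Batch structure**: lines split into two batches; batch 2 gets a
  +0.5 log-unit location shift and a 1.3× scaling of log-deviations —
  comfortably detectable, correctable effects.
* **NMR trajectories**: each feature follows a linear, saturating or
  non-monotonic day profile; informative signal enters through a ramp that
  is zero at day 1, so it lives in the day-differences by construction.
* **Blanks and QCs** (`generate_blanks_and_qcs()`): blanks at 1/1000 of
  the experimental signal, pooled QCs at the per-feature experimental mean
  with 5% noise; planted blank-dominated features sit at half the
  experimental mean (failing the 5× rule) and planted QC-absent features
  are zeroed in 60% of QC injections (failing the 50% rule).

What the generator does *not* emulate: chromatographic drift and peak-shape
pathology, m/z-dependent noise, NMR spectral overlap and alignment error,
annotation ambiguity, and any real biochemical correlation structure
between features (non-informative features are independent). Passing tests
therefore demonstrate that the *statistical machinery* behaves as claimed
under the assumed structure — not that real studies of this size will
yield panels this clean.

# Numerical choices and degenerate inputs

* All randomized operations take an explicit integer seed and restore the
  caller's RNG state; reruns are bit-identical (the pipeline manifest
  hashes every artifact to make this checkable).
* R² is undefined for a zero-variance response: an error everywhere except
  inside the SR engine, where a constant response yields R² = 0 by
  convention so that "no expression can beat the constant" remains true.
* Ties: grid search takes the first grid point; top-fraction selection
  breaks importance ties by stable input order; the variance filter
  prefers the smaller fraction.
* Zero-variance features autoscale to 0 with a warning; features with zero
  within-batch variance skip batch correction with a warning; a
  zero-median sample is an error naming the sample.
* Cross-validation folds are as equal as possible (10 samples / 5 folds →
  2 per fold); held-out R² within a fold uses the held-out mean and folds
  with zero held-out variance are dropped from the average.

# Problem sizes used by the test-suite

The default synthetic study is 10 lines × 200 features per platform with 5
informative features at effect size 3 SD, 10 replicate NMR flasks, 2
batches — the regime the framework targets. Property-style checks run
10–20 seeds of the relevant chain; the screening-calibration check runs
500 null replicates at 200 features; the brute-force oracles cover 200
random consensus instances and every hypergeometric configuration up to a
background of 12. The per-dataset symbolic-regression runs inside the
pipeline default to 6 restarts × population 120 × 25 generations, which
recovers planted laws reliably at these dimensions while keeping a full
pipeline run in minutes on one core.

# Known limitations

* Ten samples is tiny. Every importance ranking is noisy at this n; the
  consensus rule reduces, but cannot eliminate, the entry of
  chance-correlated features into panels. With 200 features and 10 lines a
  handful of pure-noise features will genuinely out-correlate the weakest
  planted feature, and no selector can tell them apart; panels should be
  read as enriched-for-signal, not pure.
* LOO-R² with full-data hyperparameter and feature selection is
  optimistically biased, by design fidelity to the protocol reproduced.
* The SR engine is a generic GP implementation: it reproduces the *rules*
  (qualifying-set thresholds, presence statistics), not any proprietary
  engine's specific model forms.
* The enrichment module tests over-representation only; it knows nothing
  of pathway topology.
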