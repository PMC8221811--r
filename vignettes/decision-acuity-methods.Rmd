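---
title: "Deriving decision acuity and its connectivity signature: models and methods"
author: "dacuity package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving decision acuity and its connectivity signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models

Decision-making ability, measured across many laboratory tasks, covaries:
people who learn fast, discount the future little and choose with low
variability in one task tend to do so in others. `dacuity` implements a
complete analysis chain for studying this shared dimension — called
*decision acuity*, `d` — in an adolescent/young-adult accelerated
longitudinal cohort:

1. a **psychometric stage** that derives `d` as the first common factor of a
   32-measure decision battery (7 tasks), with an exploratory-confirmatory
   split-sample design, and validates its construct stability;
2. a **trust-game stage** computing exchange-strategy metrics (initial
   trust, cooperativeness, responsiveness) from round-by-round
   investor-trustee contributions;
3. a **connectomic stage** that partitions a resting-state functional
   connectivity (rsFC) graph into modules by consensus Louvain clustering
   and predicts `d` (and an IQ composite) from partial-correlation edge
   features with a bagged sparse-PLS nested cross-validation pipeline,
   including permutation inference, module-wise "virtual lesion" scans,
   phenotype specificity by partial correlation, and transfer of baseline
   models to follow-up scans;
4. an **association stage**: linear mixed-effects models with participant
   random intercepts linking `d` to age and covariates, with age decomposed
   into between- and within-subject components.

Because the cohort data this design targets are access-restricted, the
package ships a first-class synthetic generator that emulates the data
structure with known ground truth; every pipeline property is validated
against that truth.

## The synthetic cohort generator

`cohort_spec()` + `generate_measure_table()` draw a baseline wave of `n`
subjects in 5 equal age bins spanning 14–24 years, and a follow-up wave
(default retention 0.70) about 18 months later (±6 months jitter). Latents
per subject and wave:

$$d_w = \beta_{age} z(\mathrm{age}_w) + b_v\,v + b_m\,m + s\,g + \sigma_e\,e_w$$

where $v, m$ are stable, age-orthogonal IQ trait latents (correlated 0.45),
$g$ a stable acuity trait and $e_w$ occasion noise. $s$ and $\sigma_e$ are
solved in closed form so that $\mathrm{Var}(d) = 1$ and the between-wave
latent correlation equals `retest_r` (default 0.68). Because the IQ
pathway is age-orthogonalized, `beta_age` (default 0.24) is *exactly* the
standardized slope of latent `d` on age, making parameter-recovery tests
unambiguous. Raw IQ subscores additionally load on age (loading 0.35), as
raw ability scores do in this age range.

The 32 measures follow a common factor plus three task-specific factors
(discounting, information gathering, economic risk; loadings 0.50), with
uniqueness completing each measure's variance to 1. The default common
loading pattern is signed and sparse — negative on decision-noise and
discounting measures, positive on outcome sensitivity, learning rates and
trust — and strong enough that the cross-task factor is the leading
dimension of the battery, as in the design being emulated. A fixed subset
of six measures (`skewed_measure_idx()`) is stored exponentiated so the
transform-selection step has real work; missingness is MCAR (default 2%).

Connectivity (`connectivity_spec()` + `generate_connectivity()`): each
subject's symmetric 168×168 matrix (defaults; any size works) is a modular
block template (14 planted modules; within/between weights 0.25/0.02 on the
partial-correlation scale) plus i.i.d. edge noise (SD 0.10), plus linear
per-edge effects of standardized `d` and IQ on planted edge sets, plus
additive site, head-motion (FD) and brain-volume confounds on *all* edges —
the simplest confound model that makes deconfounding necessary. The default
planted signal is 12 edges with slope 0.019; with per-edge correlation
$\rho = e/\sqrt{e^2+\sigma^2} \approx 0.19$, the total planted variance is

$$R^2 = \frac{m\rho^2}{1 + (m-1)\rho^2} \approx 0.30 .$$

A *diffuse* signal of the same total $R^2$ spread over 50 edges has
per-edge $\rho \approx 0.10$, which the pipeline's own univariate prefilter
(p < 0.05) mostly discards; concentrating the default signal keeps the
planted effect recoverable *by the pipeline under study*, which is the
point of the validation. Both the edge set and the slope are user-facing
fields.

What the generator deliberately does **not** emulate: spatial structure of
real parcellations, heavy-tailed or motion-coupled edge noise,
non-linear age effects, selective attrition, or measure-level retest
reliabilities (stability is injected at the latent level only, since the
study design reports none at measure level). Passing tests therefore
demonstrate the *pipeline's* correctness and calibration under the stated
generative assumptions, not properties of any real cohort.

## Preprocessing decisions

* **Transforms.** Family fixed to identity, shifted log
  $\log(x - s)$ — with shift $s = 0$ for strictly positive measures and
  $s = \min - \varepsilon$, $\varepsilon = 10^{-6}\times$range, otherwise
  (shifting positive data to its minimum would manufacture left-tail
  outliers) — and signed powers $\mathrm{sign}(x)|x|^p$,
  $p \in \{1/3, 1/2, 2\}$; selection minimizes |sample skewness|, and a
  measure already near-normal (|skewness| < 0.2) keeps the identity, so
  only measures that need gaussianizing are touched. All members are
  monotone on the observed range, and the fitted parameters are stored so
  follow-up data are transformed *identically* and z-scored with baseline
  means/SDs.
* **Imputation.** Iterative low-rank SVD completion; the rank (1–6) is
  chosen by masking an extra 5% of observed cells and minimizing
  reconstruction RMSE, ties to the smaller rank. Observed cells are never
  altered.
* **Composites.** Aggregate performance = mean of within-task t-scores
  (mean 50, SD 10) of winnings in the four tasks scored this way; the IQ
  composite = mean of the two z-scored raw subscores.

## Factor pipeline decisions

* **Extraction** is minimum-residual (minres): uniquenesses optimized so
  the rank-k eigen-approximation minimizes squared off-diagonal residuals.
* **Rotation** is quartimin (oblimin family) via the oblique
  gradient-projection algorithm. The solution is reported as pattern,
  structure and factor-correlation matrices.
* **Factor 1 identification.** After an oblique rotation, a task-specific
  factor that absorbs its members' shared variance can out-rank the
  cross-task factor by explained variance. Factor 1 is therefore defined as
  the factor whose salient loadings (|λ| ≥ 0.25) span the most *tasks*
  (explained variance breaks ties); the rest are ordered by explained
  variance. This matches how the construct is defined — the one factor that
  loads on measures from multiple tasks. Signs are chosen so most salient
  loadings are positive.
* **Recovery comparisons use the structure matrix** (measure-factor
  correlations): the generator's planted factors are orthogonal, so planted
  loadings *are* measure-factor correlations; comparing them with an
  oblique pattern matrix would systematically understate recovery.
* **Confirmatory stage.** For each exploratory k, the salient loadings —
  |structure loading| ≥ 0.25, i.e. measure-factor correlations, the scale
  on which salience is interpretable for an oblique solution — are freed
  and the model is fitted by maximum likelihood to the held-out half
  (standardized latents, free factor correlations, free uniquenesses;
  analytic gradients; the factor correlation matrix is parametrized
  through a row-normalized Cholesky factor so it stays positive definite).
  A factor needs at least 3 freed indicators (the standard identification
  rule) or its k is excluded; a fit whose factor correlations approach ±1
  or whose pattern loadings turn quasi-Heywood is inadmissible and counts
  as non-converged — in practice these two screens are what eliminate
  overfactored models, the same role non-convergence plays in
  off-the-shelf SEM fitters. Selection: the largest identified, converged
  k whose BIC (χ² + q·log n, rank-equivalent to −2logL + q·log n for model
  comparison) improves on the previous such model, scanning the whole
  candidate range because single-k BIC fluctuations are common at these
  sample sizes. CFI uses the independence baseline; the RMSEA 90% interval
  comes from noncentral-χ² root finding.
* **Scoring** uses regression (correlation-preserving) weights
  $W = R^{-1} L \Phi$; subset scoring (e.g. the six longitudinally assessed
  tasks) zeroes weights outside the subset without renormalizing, keeping
  the score on a conservative, comparable scale.
* **Split-half stability** cross-scores by default with single-factor
  (k = 1) extractions: the construct under study is the cross-task common
  dimension, and the one-factor solution isolates it without the
  rotational indeterminacy that makes multi-factor weight vectors noisier
  across resamples.

## Trust metrics

For rounds $t \ge 2$: $\Delta I = (I_t - I_{t-1})/\mathrm{endowment}$ and
$\Delta T = R_t/(3I_t) - R_{t-1}/(3I_{t-1})$ — both changes in the fraction
of money *available* to give. An investment of zero with a positive return
is invalid; zero investment otherwise contributes a trustee fraction of 0.
The move class follows the angle of $(\Delta I, \Delta T)$, labels assigned
in order as the angle rises from −180° to 180° (retaliating, repairing,
honoring, disrupting), quadrant boundaries closed on the upper edge. The
resultant (sum of nonzero round vectors) gives the orientation;
responsiveness is its length divided by (rounds − 1) — the normalization is
a documented convention, the design source does not state one.
Cooperativeness projects the unit vector at the orientation onto the chord
between the two empirically observed strategy poles — unit vectors at
−135° (mutual reduction, score 0) and 0° (coaxing, score 1) — and clips to
[0, 1]; the poles are fixed rather than refit per dataset because refitting
a data-dependent line would make scores incomparable across datasets.

## Network modules

Subjects with mean FD > 0.3 mm are excluded first. The group-mean matrix
(negatives clipped to zero) is clustered by weighted Louvain at resolution
γ with random restarts, then refined by single-node best-move passes
(Kernighan–Lin style) until no reassignment improves modularity
$Q = \tfrac{1}{2m}\sum_{ij}[W_{ij} - \gamma k_ik_j/2m]\,\delta(c_i,c_j)$.
The consensus procedure gathers 100 (configurable) runs into a
co-assignment frequency matrix, which is itself re-partitioned (resolution
1, as in the standard consensus scheme; the consensus matrix lives on a
different scale than the data) until all runs agree; no threshold is
applied to the consensus matrix. Resolution tuning computes a consensus
partition per grid value and picks the γ with maximal mean NMI
(arithmetic-mean entropy normalization) against the partitions at the
*adjacent* grid values — a stability-plateau criterion; ties go to the
smaller γ. The adjacent-γ reading of "stability across resolutions" is a
documented choice; within-γ run-to-run agreement is the other reading.
Edge features are vectorized from the upper triangle in row-major order
(i < j, fixed node order) everywhere, so feature indices are stable across
modules.

## The SPLS prediction engine

`fit_spls()` builds an active set over K steps: the cross-covariance
direction $z = X^\top y$ (y the current residual) is soft-thresholded at
$\eta\,\max|z|$; survivors join the active set; coefficients are refitted by
dense NIPALS PLS on the union active set. At η = 0 this *is* dense PLS
(verified against an independent closed-form Krylov-subspace oracle to
1e−8); as η → 1 only the argmax feature survives.

`nested_cv_predict()` per outer fold: the target (never the features) is
residualized for age, sex, age×sex, brain volume, site indicators, FD and
denoising DOF using training-row coefficients only; features are
standardized by training statistics; the univariate prefilter (p < 0.05)
runs once per training partition (not per bootstrap resample — it is a
speed step that precedes the model); (η, K) are selected by inner k-fold CV
on minimum MSE, ties to the sparser model (larger η, then smaller K); a
bagged model (default 200 bootstrap resamples, coefficient vectors
averaged, selection frequencies recorded) predicts the test fold.
Performance is the mean over repeats of the per-repeat correlation between
residualized observed and predicted scores.

**Fold assignment is uniformly random, not stratified by the target.** The
permutation null reuses the observed fold structure and the fold-selected
hyperparameters; if folds were built from the target, the observed
statistic would not be exchangeable with its permutation replicates, and
measured type-I error drifts off nominal. With random folds the null
p-values are uniform (Kolmogorov–Smirnov check in the test suite) and
empirical type-I error sits inside the binomial envelope of 5%.

**Permutation inference** permutes the already-residualized target within
the whole sample, refits prefilter + bagged model per fold, Fisher-
transforms the null correlations, and estimates the SD of a zero-centered
Gaussian null ($\hat\sigma_z = \sqrt{\mathrm{mean}(z^2)}$); the one-tailed
p-value of the observed Fisher-z follows. Because the null is parametric in
the tail, p-values below 1/N_P are meaningful.

**Virtual lesions** refit the whole pipeline per module on the edges
touching that module (within + boundary connections) plus the
all-connections model, with Benjamini–Hochberg correction across all tests.
**Specificity** evaluates the partial correlation of observed vs predicted
controlling the competing phenotype — itself first residualized on the
covariate design, so all three variables live on the confound-free scale —
on every permutation refit, so its p-value uses the same null machinery. **Transfer** applies each baseline
fold model (deconfounding coefficients, feature standardization, bagged
weights) to follow-up data of that fold's *test* subjects only, so no
subject is predicted by a model that saw their baseline data; with
identical inputs, transfer predictions are bit-identical to baseline
out-of-fold predictions.

## Associations

`fit_lme()` fits a REML mixed model with participant random intercepts
(random age slopes omitted: in the emulated design they worsen fit). Age
enters as the subject's mean (between, cross-sectional) and the occasion's
deviation (within, longitudinal); a Wald χ²(1) tests their equality.
Standardized betas are reported alongside raw ones. Singular fits fall back
to an attached OLS comparison with a warning.

## Problem sizes and numerical choices

Validation runs use deliberately compact problem sizes chosen to exercise
every code path with tight Monte-Carlo error: factor recovery at n = 800
(20 replicates), permutation calibration on 50 null datasets of n = 150
with 300 features and 50 permutations each, signal recovery on 40-node /
8-module graphs at n ≈ 300 with a planted within-module signal of 5 edges
totalling R² ≈ 0.3, community detection on the full 168-node / 14-module template
plus exhaustive-search checks on ≤ 8-node graphs (all set partitions
enumerated), and LME recovery over 50 replicates at n = 600. Tolerances:
SPLS dense-limit agreement 1e−8; optimizers use analytic gradients for the
CFA (loadings/uniquenesses; the few factor-correlation parameters use
numerical differentiation of the Cholesky map); minres uses L-BFGS-B with
uniquenesses bounded in [0.005, 1]; ties in model selection always resolve
toward the sparser/smaller model.

## Known limitations

* The CFA assumes an unstructured, freely correlated factor model with the
  0.25 salience threshold; hierarchical or bifactor alternatives are out of
  scope.
* The permutation null treats the residualized target as exchangeable;
  under strong confound misspecification this is approximate.
* Virtual-lesion feature sets overlap across modules (boundary edges belong
  to two modules), so neighboring modules of a true source can carry real
  signal; the tests therefore plant within-module signals when asserting
  localization.
* The trust-game generator implements stylized strategy archetypes, not a
  model of any real partner policy.
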