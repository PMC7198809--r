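---
title: "Methods: voxel-wise linear-SVM discrimination of diffusion maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise linear-SVM discrimination of diffusion maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical procedure it
implements, the choices that were genuinely open when it was designed, and
what its synthetic-data tests do and do not demonstrate about real data.

## The model

`voxsvm()` addresses individual-level discrimination between two groups —
healthy controls (HC, coded $+1$) and patients (coded $-1$) — from
registered scalar diffusion-metric volumes, typically fractional anisotropy
(FA) maps in a common template space. The pipeline assumes spatial
normalisation has already happened: every subject lives on the identical
voxel grid, and a voxel is a feature.

**Masking.** Features are the voxels whose across-subject mean value exceeds
a threshold (default 0.2 FA, the standard white-matter convention). The
in-mask voxels are enumerated in R's column-major array order; this scan
order fixes the feature-to-voxel correspondence everywhere downstream.

**Fisher ranking.** For feature $q$ with group means $\bar{x}_q^{(1)},
\bar{x}_q^{(2)}$, grand mean $\bar{x}_q$, and unbiased within-group sample
variances $s_1^2(q), s_2^2(q)$:

$$F(q) = \frac{(\bar{x}_q^{(1)} - \bar{x}_q)^2 + (\bar{x}_q^{(2)} -
\bar{x}_q)^2}{s_1^2(q) + s_2^2(q)}.$$

The numerator is interclass separation, the denominator intraclass
variance; features are sorted in descending $F$. Scores are computed on the
*raw* training features — centring and normalisation are applied only to
the selected features, after selection.

**Classifier.** The top-$k$ features are z-scored with training-row
statistics and classified by a soft-margin linear SVM: minimise
$\tfrac12\|w\|^2 + C\sum_j \xi_j$ subject to $y_j(\langle w, x_j\rangle + b)
\ge 1 - \xi_j$, $\xi_j \ge 0$, solved in its dual. The penalty is fixed at
$C = 1$: in voxel-wise neuroimaging problems the feature dimension far
exceeds the sample size, the data are (near-)separable, and a fixed unit
penalty with a linear kernel is the conventional, tuning-free choice. A
decision value $f(x) = \langle w, x\rangle + b > 0$ assigns HC; $f(x) \le 0$
assigns the patient group (zero falls to the patient side by the
"otherwise" branch of the labelling rule).

**Nested leave-one-out cross-validation.** Each of the $n$ folds holds out
one subject. Fisher scores, the ranking, the top-$k$ set, the scaler and the
SVM are all pure functions of the remaining $n-1$ rows; the left-out row is
scaled with the training statistics and scored. The sweep repeats this for
$k = \text{step}, 2\cdot\text{step}, \ldots, k_{\max}$ (conventionally step
100 up to 20,000, i.e. 200 cycles, truncated to the mask size on small
grids).

**Optimal k.** Published sweeps are reported as "the plateau from $k_a$ to
$k_b$ was best, so its middle value was selected". That phrase is not a
total rule, so the package formalises it deterministically: find the
maximal accuracy, take the *longest contiguous run* of grid points attaining
it (earliest run on ties), and return the run's midpoint snapped *down* to
the grid. A maximal run over 1,400–3,400 on a step-100 grid yields 2,400; a
run over {100, 200} yields 100.

**Inference.**

* *Permutation test*: group labels are shuffled over all subjects and the
  entire leakage-free LOOCV at the fixed optimal $k$ is re-run per
  permutation (ranking and scaling recomputed under the permuted labels
  inside every fold). The reported p-value is the plug-in
  $\#\{\text{null} \ge \text{observed}\}/N$, which can be exactly zero; the
  never-zero $(\#+1)/(N+1)$ estimate is returned alongside. Permuting only
  at the selected $k$ (rather than re-running the whole sweep) matches the
  convention of reporting the null distribution "at the optimal feature
  count"; note it does not account for the selection of $k$ itself.
* *ROC/AUC*: decision values are swept over their unique thresholds
  (HC = high-value class); the trapezoidal AUC equals the rank statistic
  $P(\text{random HC value} > \text{random patient value})$ with ties
  counted $\tfrac12$, which the tests assert on every instance.
* *Clinical correlation*: Spearman's rank correlation (mid-ranks on ties,
  large-sample t p-value, via `stats::cor.test`) between patient decision
  values and their severity scores, patients only — controls carry no
  score.

**Discriminative map.** Fold weight vectors live on fold-specific feature
sets, so each is scattered to its own selected voxels in the full
$m$-dimensional space (zeros elsewhere) before averaging; averaging over
only commonly selected features would discard most of the map. The average
is back-projected to a volume. Weights are kept in the z-scored feature
space in which they were learned — the map reads as standardised-metric
discriminability, and the sign convention (positive = patient value lower
than control value) is unaffected by the scaling. The map is thresholded
*per sign* at a fraction (default 10%) of the positive maximum and of the
absolute negative minimum respectively, and connected components
(26-connectivity by default; 6 and 18 available) of at least `min_size`
voxels (inclusive $\ge$, default 20) are tabulated with signed peak weight
and peak coordinate, sorted within sign by descending absolute peak.

Per-sign thresholding is a deliberate reading: under a global-|max|
threshold, a map whose strongest weight is negative would silently discard
weak-but-real positive clusters whose peaks fall below 10% of that global
maximum, which contradicts how such cluster tables are reported in
practice. The inclusive $\ge 20$ size filter likewise keeps exactly
20-voxel clusters.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `mask_threshold` | 0.2 | FA | standard white-matter mean-FA mask |
| `smooth_fwhm` | 6 | mm | common FA smoothing kernel; sigma = fwhm / (2√(2 ln 2) · voxel) voxels per axis |
| `C` | 1 | — | fixed, tuning-free soft-margin penalty |
| `k_max`, `k_step` | 20,000, 100 | features | the 200-cycle sweep convention |
| `map_fraction` | 0.10 | — | per-sign map threshold |
| `min_cluster` | 20 | voxels | inclusive cluster-size filter |
| `connectivity` | 26 | — | neuroimaging cluster-reporting default |

## The synthetic cohort generator

`simulate_cohort()` emulates a two-group DTI study so the pipeline can be
exercised and calibrated without patient data. Per subject: baseline FA
plus i.i.d. Gaussian voxel noise, Gaussian-smoothed at `smooth_fwhm` (so the
noise is spatially correlated the way smoothed FA maps are), then — for
patients — each planted sphere adds `multiplier × delta`, and values are
clipped to $[0, 1]$. The per-patient severity multiplier is
$\mathcal{N}(1, 0.3)$ clamped to $[0.1, 1.9]$; the clinical score is
`score_intercept + score_slope × multiplier + noise`. With the default
negative slope ($55 - 15\,m + \mathcal{N}(0,4)$), severer synthetic
patients have both stronger FA reductions and lower scores (mean ≈ 40,
sd ≈ 7, an ALSFRS-R-like scale), which makes a positive decision-value /
score correlation recoverable by construction.

Defaults mirror a typical single-site study: 22 patients vs 26 controls on
a 48³ grid of 2 mm voxels, baseline FA 0.45, pre-smoothing noise sd 0.1
(post-smoothing voxel sd ≈ 0.010), and thirteen planted spheres — ten with
patient FA reduced and three increased, matching the 10-vs-3 split of
discriminative directions typical of reported cluster tables. One RNG
stream is seeded per cohort; per-subject sub-seeds are drawn from it first,
so generation is bit-reproducible.

What the generator does **not** emulate: registration error, anatomy-shaped
lesions (effects are spheres of constant delta), field inhomogeneity,
site/scanner effects, or any tensor-level physics. Passing tests therefore
demonstrate the *pipeline's* correctness and calibration — leakage freedom,
effect recovery, nominal type-I error — not clinical performance on real
cohorts.

## Numerical choices

* **SVM solver**: deterministic sequential minimal optimization on the dual,
  maximal-violating-pair working-set selection, zero initialisation, no
  randomness; violation tolerance $10^{-8}$, iteration cap 200,000.
  Multipliers within $10^{-12} C$ of a bound are snapped onto it — otherwise
  floating-point residue (an $\alpha \sim 10^{-17}$) re-admits immovable
  points into the selection and stalls the solver. The bias $b$ is averaged
  over free support vectors ($0 < \alpha < C$), falling back to the
  KKT-interval midpoint when all multipliers are at bounds. The tests check
  the solution against a brute-force active-set QP enumeration (objective
  and $w$ within $10^{-6}$), full KKT feasibility, the duality gap, and an
  independent libsvm implementation.
* **Scaler**: "normalisation" is z-scoring — unit *sample* standard
  deviation per selected feature, training rows only (published
  descriptions pair it with mean centring but rarely pin the norm; unit
  variance is the standard reading and the declared choice here). Standard
  deviations are floored at $10^{-8}$ so within-training constant features
  map to 0 rather than NaN.
* **Degenerate Fisher scores**: denominator 0 with numerator 0 gives
  $F = 0$; denominator 0 with positive numerator gives $F = +\infty$, which
  ranks first — a perfectly separating within-group-constant feature is
  maximally discriminative, the limit of the ratio.
* **Ties**: feature ranking is a stable descending sort with ascending
  voxel-index tie-break; cluster labels order by descending size then first
  voxel in scan order; tied peak weights take the first voxel in scan order.
  All deterministic and platform-independent.
* **Smoothing boundary**: half-sample (edge-repeating) reflection. With a
  normalised symmetric kernel this makes the 1-D convolution operator
  symmetric and doubly stochastic, so constants and the global mean are
  preserved *exactly* and the variance never increases — properties the
  tests assert. (Whole-sample mirroring would preserve constants but not
  the exact global mean.)
* **Coordinates**: 1-based voxel indices, R's convention, used consistently
  in all reports; world/MNI coordinates are emitted only when a volume
  carries an affine (which maps 0-based indices, per NIfTI).
* **Cohort preconditions**: Fisher scores need at least two members per
  group in every training split, so LOOCV requires at least three subjects
  per group.

## Problem sizes used by the test suite

Test cohorts are generated at desk scale, chosen so the full suite runs in a
few minutes while each property remains sharply testable: unit tests use
4–10 subjects per group on 4³–8³ grids; effect recovery uses 24 + 24
subjects on a 32³ grid with one 33-voxel planted sphere (radius-2 discrete
ball) at `delta = 10 × noise_sd`; permutation calibration uses 200
effect-free cohorts of 8 + 8 subjects on 8³ grids with 200 permutations
each, checking that the empirical rate of $p \le 0.05$ sits inside the
binomial 95% band around 0.05.

## Known limitations

* With $k$ larger than the training-set size the linear SVM interpolates:
  even when every signal voxel is selected, the max-margin direction also
  recruits noise features, and a held-out subject can occasionally flip.
  Perfect LOOCV labelling on near-separable synthetic cohorts at $k = 100$
  is therefore a property of a fixed instance, not of every seed; the
  permutation test, not the raw accuracy, carries the inference.
* The permutation test fixes $k$ at the selected optimum, so the sweep's
  selection optimism is not propagated into the null (a stricter full-sweep
  permutation would re-run all 200 cycles per shuffle).
* Accuracy on LOOCV with balanced small cohorts is slightly pessimistic
  (the held-out subject's class is always the training minority); the
  null-calibration test accounts for this because observed and permuted
  accuracies share the bias.
* The plug-in permutation p-value can be exactly 0 and is biased low by one
  rank; both estimates are reported.
* Reported cluster coordinates are voxel indices unless an affine is
  present; the synthetic generator uses none.
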