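---
title: "Functional-connectivity subtyping and PLS: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-connectivity subtyping and PLS: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsubtype)
```

This vignette documents the statistical model behind `fcsubtype`, the
parameters that matter and their defaults, what the synthetic cohort
generator does and does not emulate, and the numerical and design choices
made where the methodology left room.

## The pipeline in one paragraph

Per-subject ROI time series are truncated to a common length (the cohort
minimum; 145 timepoints in the reference design), converted to Fisher-z
Pearson correlations over all ROI pairs, and vectorized in a fixed
lower-triangle order (for R ROIs, R(R−1)/2 connections; 12,720 at R = 160).
Age and acquisition site — site coded as a Helmert contrast basis — are
regressed out of every connection. Subjects are clustered by k-means under
the cosine distance, with the number of clusters chosen by an elbow
criterion whose reliability is assessed on 500 random half samples.
Mean-centering PLS then contrasts the resulting subtype-by-diagnosis groups;
behavior PLS relates FC to a five-measure behavior battery within groups.
Pattern significance comes from permutation tests on singular values,
salience stability from bootstrap ratios (BSR), and network-level structure
from a permutation test on block-averaged thresholded BSR maps.

## Connectivity and confound removal

Correlations are clipped to ±(1 − 1e−12) before `atanh` so numerically
perfect correlations stay finite. The confound design is
`[intercept, centered age, Helmert(site)]`. Two details deserve emphasis:

* **The grand mean is retained by default** (`residualize(mode =
  "keep_mean")` returns OLS residuals plus the intercept estimate). Cosine
  distance is sign- and direction-sensitive, and contrast expressions
  average raw signed FC, so destroying the mean structure would change both
  downstream analyses. `mode = "residual"` gives mean-zero residuals for
  users who prefer them.
* **The Helmert variant is immaterial for residuals.** Any full-rank coding
  of site spans the same column space as the site indicators, so residuals
  are identical whichever variant is used; the test suite verifies this by
  reversing the level order. Age is centered so the intercept stays
  interpretable as the grand mean.

Truncation keeps the first `target_length` timepoints; nothing in the
correlation model favors one segment over another, and a fixed rule keeps
runs reproducible.

A report-only motion screen (`motion_association_check()`) runs a
single-group behavior PLS of FC against mean framewise displacement and the
percentage of high-motion frames and returns the first pattern's permutation
p; it never modifies the data.

## Cosine k-means and the elbow

Lloyd iterations alternate nearest-centroid assignment under
d(x, c) = 1 − cos∠(x, c) with arithmetic-mean centroid updates, stopping
when assignments no longer change (cap: 300 iterations, with a warning).
Choices the method description leaves open, fixed here:

* **Initialization and restarts.** Initial centroids are k distinct random
  subjects; `cosine_kmeans()` keeps the best of 20 restarts by mean cosine
  distance. Within the 500-resample reliability sweep (`bootstrap_k()`) the
  default drops to 3 restarts per k — across the sweep the elbow choice is
  an aggregate over 500 × 8 fits, which is far less sensitive to any single
  local optimum than a single full fit, and the sweep stays tractable on one
  CPU.
* **Empty clusters** are reseeded with the point farthest (cosine) from its
  current centroid — deterministic given the seed.
* **Half sampling is without replacement.** The reliability procedure draws
  50% of subjects at random per resample; this is subsampling, not a
  classical bootstrap, and the package implements it as described.
* **Elbow statistic.** `slope_change(k) = (D(k−1) − D(k)) − (D(k) − D(k+1))`,
  i.e., the second difference of the distance curve, maximized over
  2 ≤ k ≤ k_max − 1 with ties broken toward smaller k; k = 1 is always
  fitted as the reference point and k_max defaults to 8.

A caveat on the update rule: the arithmetic mean is the exact minimizer of
squared Euclidean distance, not cosine distance, so strict monotonicity of
the objective across iterations is guaranteed only for unit-norm rows (the
test suite checks it there). For FC vectors of similar norms the departure
is negligible; assignments are exactly scale-invariant either way.

## PLS: decomposition and inference

**Mean-centering PLS.** The groups × connections matrix of group means is
column-centered and SVD-decomposed. Centering uses the **unweighted grand
mean of group means** by default: with unbalanced groups (the usual case
after subtyping) this treats groups symmetrically, and the centered matrix
has rank ≤ g − 1 so exactly g − 1 patterns are returned. A
`center = "pooled"` switch subtracts the pooled subject mean instead, for
comparison with toolboxes that do so. Brain scores are `FC %*%
brain_salience`.

**Behavior PLS** stacks per-group behavior × connection Pearson-correlation
blocks in group order and decomposes the stack. Only complete cases enter
(no imputation), and a zero-variance behavior within any group is an error
rather than a silent drop. Behavior scores project within-group standardized
behaviors on the group's behavior-salience block.

**Permutation test.** Subjects' brain rows are reshuffled against the fixed
design (labels or behaviors), the decomposition recomputed, and the i-th
permuted singular value compared with the i-th observed one; p is the
proportion of permuted values strictly greater, reported as the floor
"< 1/n_perm" when no permuted value exceeds the observed (stored numerically
as 0 with a `p_floor` flag).

This raw pattern-by-pattern comparison is the classical procedure and is
exactly valid for the leading pattern. For later patterns it has a
structural bias the package documents rather than hides: when earlier
patterns carry real signal, permutation redistributes that signal into the
*top* permuted singular values, deflating the later ones, so a later
pattern's observed singular value — pure noise though it may be — tends to
exceed its permuted counterparts. In synthetic cohorts with a strong planted
subtype contrast and an additive diagnosis effect, the third (interaction)
pattern's raw-statistic p is near 0 essentially always, despite no
interaction being planted. Two remedies were considered. Procrustes-style
rotation of permuted patterns onto the observed structure was rejected: in
null simulations it rejected the leading pattern at ~5× the nominal rate,
because the reference directions come from the unpermuted data. Instead,
`pls_permutation(statistic = "covariance_fraction")` compares d_i²/Σd² —
a statistic computed identically on observed and permuted data, hence an
exact permutation test — which asks whether a pattern accounts for more of
the brain–design covariance than chance. Under it the planted interaction is
correctly non-significant while the leading pattern remains highly
significant. The raw statistic stays the default for fidelity to the
standard procedure; for inference on patterns beyond the first, use the
covariance-fraction statistic. Note the fraction statistic is conservative
for genuinely small later patterns: a real but modest second effect can be
dominated by the permutation redistribution of a large first effect.

**Bootstrap ratios.** Subjects are resampled with replacement within groups;
each bootstrap pattern is aligned to the original by the sign of the
brain-salience dot product (sign-only alignment — the minimal correction
that prevents trivial SE inflation; full rotation alignment is deliberately
out of scope). BSR = original salience / bootstrap SE, with |BSR| > 2 (≈95%
stability) defining the stable mask. Variances are accumulated with
Welford's algorithm so degenerate resampling (identical rows) yields exactly
zero SEs, which are flagged as non-finite BSRs and excluded from the mask
with a warning. Design-salience 95% intervals come from percentiles of the
same resamples.

**Contrast expressions** average raw (residualized) FC over connections with
BSR > +2 and, separately, BSR < −2, per group, keeping per-subject means for
plotting; an empty suprathreshold set is reported as absent (`NA`), not as
zero.

**Salience correlation** between two patterns uses Pearson r with a
permutation p from shuffling the entries of one vector
(p = proportion of |r_perm| ≥ |r_obs|).

## Network-pair contributions

Thresholding maps BSR > 2 to +1, BSR < −2 to −1, everything else to 0 —
strict inequalities, so a BSR of exactly ±2 maps to 0. For each unordered
network pair the positive (negative) contribution is the signed fraction of
the pair's connections carrying +1 (−1); within-network blocks count
n(n−1)/2 pairs (no self-connections). The permutation null reorders the sign
vector over connection positions, preserving its multiset exactly, with
p for positive entries the proportion of permuted contributions ≥ observed
and for negative entries the proportion ≤ observed — the signed analogue, in
each entry's own direction, of a magnitude rule.

## Cohort statistics

Group comparisons use the pooled-variance two-sample t (the form whose
degrees of freedom are n1 + n2 − 2, matching how such tables print df),
computable directly from mean/SD/n summaries, and plain Pearson chi-square
without continuity correction. Exclusion boundaries are strict on the
exclusion side: age exactly 40, IQ exactly 75, mean FD exactly 0.20 mm and
exactly 20% high-motion frames are all retained. One known print
discrepancy is documented in the package rather than chased: handedness and
eye-status contingency rows of the published-style reference table do not
reproduce from their printed counts under Pearson (with or without
continuity correction), so they are excluded from closed-form checks.

## The synthetic cohort generator

`cohort_spec()` defaults define the standard validation cohort: 200
subjects, 160 ROIs in six networks, 5 sites, per-subject series lengths
uniform in [145, 180], subtype fraction 0.5, ASD fraction 145/266, subtype
effect 0.3 z (added to within-network, subtracted from between-network
connections for subtype 2), diagnosis effect 0.2 z on a fixed random 10% of
connections, site offsets spanning ±0.06 z, age slope 0.005 z/year,
behavior loading 1, and residual z-noise 0.2. Effects are planted
*additively in Fisher-z space* and mapped through tanh to correlation space
before covariance assembly, so planted saliences are directly comparable to
what the z-space analysis should recover. Non-positive-definite targets are
repaired by clipping eigenvalues at 1e−6 and re-symmetrizing. Behavior noise
is Gaussian with SD 5 × noise_sd (unit SD at the default), so the noiseless
limit is exact. The six network sizes (34, 21, 32, 22, 33, 18) are a
configurable fixture summing to 160, not a claim about any published
parcellation.

Two honest consequences of this construction:

* **The tanh map and PD repair compress strong planted blocks**, so the
  realized group separation is smaller than the nominal z offsets,
  increasingly so at small ROI counts. They also make planted site and age
  effects slightly nonlinear in measured z-space, of which linear
  residualization removes only the linear part. At full scale the planted
  subtype contrast dominates these residual curvatures by an order of
  magnitude; at strongly reduced dimensionality it need not, which is why
  reduced-size unit fixtures isolate single effects.
* **Noise is independent across connections and subjects.** Real FC noise is
  spatially correlated and subject-structured (arousal, residual motion,
  vascular effects). Passing tests therefore demonstrate the estimators'
  correctness and calibration under the planted model, not robustness to
  every real-data artifact; in particular, real between-subject covariance
  spectra are heavier-tailed than this generator produces.

The generator does not simulate voxel-level fMRI, scanner physics, or
realistic motion; motion metrics are phenotype columns only, uncoupled to
the planted FC (which is what makes the motion screen's null behavior
testable).

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed, and a master seed fans out
to per-stage streams through a fixed string-hash derivation, so stages rerun
in isolation reproduce the pipeline run exactly; cohorts are bit-identical
given (spec, seed). The validation suite runs the full standard cohort
(n = 200, 160 ROIs) for subtype recovery and the 500-resample reliability
sweep; PLS interaction behavior is profiled over 20 seeds at n = 120 with
24 ROIs and 200 permutations; null calibration uses 200 replicate cohorts of
24 subjects with 10 ROIs and 60 permutations — sizes chosen so each check
measures what it claims at desk scale while the whole suite remains a
single-CPU run.

## Known limitations

* Raw-statistic permutation p-values for patterns beyond the first are
  anticonservative in the presence of strong leading patterns (see above);
  the covariance-fraction statistic is the supported alternative, and is
  itself conservative for small real effects.
* Cosine k-means with mean updates is a local optimizer; restarts mitigate
  but do not eliminate local optima, and the elbow criterion inherits the
  usual ambiguity when distance curves are nearly linear (the tie rule
  prefers the smaller k).
* Linear confound regression removes linear site and age structure only;
  nonlinear site or development effects survive it.
* The behavior battery is modeled as a linear function of one latent FC
  pattern plus independent noise; real batteries are discrete, bounded,
  skewed, and multi-factorial.
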