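---
title: "Difference-matrix connectome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference-matrix connectome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectodiff)
```

# Overview

`connectodiff` analyses small two-group rodent MRI cohorts along three
axes: functional connectivity (BOLD fMRI), regional brain volumetry
(labelled structural images), and gross vascular volume (time-of-flight
angiography). This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the choices made where the design was genuinely open.

# The functional-connectivity model

## Connectome construction

Each subject's preprocessed region series (frames × regions) is reduced
to a **connectome**: the matrix of Pearson correlations between all
region pairs. Raw `r` values are stored and compared directly — no
Fisher z-transform by default — because all downstream statistics
(difference vectors, pattern correlations, point-biserial `R²`) are
themselves correlations of these values, and the bounded scale is the
natural one for edge-wise subtraction. Edges are vectorised in a single
canonical order (strict upper triangle, row-major), each classed as
intra-left, intra-right or inter-hemisphere from the region table.

Preprocessing in region-series mode applies, in fixed order, a
zero-phase Butterworth band-pass and global-signal regression. Voxel
mode adds brain masking before and Gaussian smoothing after. Defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| passband | 0.008–0.2 | Hz | resting-state band at TR 1.8 s |
| filter order | 2 (×2 passes) | – | zero-phase forward–backward; order configurable |
| smoothing FWHM | 0.3 | mm | ~1.1 voxel at 0.275 mm isotropic |
| edge threshold | R² > 0.2 | – | discriminative-network binarisation |
| vascular thresholds | 7000/7500/8000 | intensity | held constant across subjects |

The Butterworth design order is applied forward and backward
(`filtfilt`-style), giving zero phase and an effective order of twice
the design order, with reflective padding of 3 × order samples at each
end. The global signal is the unweighted mean across in-mask voxels
(voxel mode) or regions (region mode); regression includes an
intercept, and an optional linear-trend regressor sits behind
`detrend_global` (default off) since a mean-only regression is the
conservative reading of standard practice. Smoothing uses
σ = FWHM/(2√(2 ln 2)) per axis in voxel units, with the kernel
renormalised inside the mask so no intensity bleeds in from zeroed
background and the in-mask mean is preserved.

## Difference matrices and class patterns

For subjects *i*, *j*, the **difference vector** is
`D_ij = edges(C_i) − edges(C_j)`. Within-group pairs are unordered and
counted once; cross-group pairs are oriented control − cKO. Two
aggregate statistics are computed:

- **Pairwise pattern similarity** — the mean squared Pearson
  correlation between difference vectors, either across two classes or
  among all distinct pairs within one class. Because every quantity is
  squared, the statistic is invariant to each pair's arbitrary
  subtraction orientation. Significance comes from an edge-label
  permutation null (default 10,000 seeded draws): each draw permutes
  the edge axis of one side, destroying edge alignment while preserving
  each vector's value distribution.
- **Class pattern** — the per-edge root-mean-square of difference
  values across a class's pairs, i.e. how strongly each edge varies
  between subjects of that class. RMS (not mean) is used because
  orientation is arbitrary. The Pearson correlation between the
  control–control and cKO–cKO patterns measures whether the same edges
  carry subject identity in both groups.

How a single summary `R²` between two classes of difference matrices
should be computed is genuinely underdetermined; both the mean-pairwise
form and the RMS-pattern correlation are implemented (the RMS pattern
is the default for class-versus-class questions), and neither is
claimed to reproduce any particular historical value — on real data the
numbers depend on cohort idiosyncrasies that no simulation reproduces.

## The discriminative network

Per edge, `R²` is the squared **point-biserial correlation** between
edge strength and the binary group label across subjects. This is the
simplest statistic consistent with "edges that can differentiate the
groups": it is monotone in the two-sample t statistic
(`t² = R²(n−2)/(1−R²)`), making its null tractable. Edges with
`R²` above the threshold (default 0.2) form the network; each retained
edge is signed by the direction of the group difference (+1 = higher
synchrony in cKO). The statistic is isolated in one function so
alternatives (e.g. rank-based) can be swapped. Edges with zero variance
across subjects get `R² = 0` with a warning rather than an error, since
a degenerate edge carries no discriminative information.

Under the null (no group effect, subjects exchangeable),
`R²(n−2)/(1−R²) ~ F(1, n−2)`, so the expected fraction of null edges
passing the threshold at n = 12 is
`pf(0.2·10/0.8, 1, 10, lower.tail = FALSE) ≈ 0.145`. This is worth
internalising: **at a 12-subject cohort, roughly one in seven null
edges crosses R² = 0.2 by chance**, so the network's meaning at small n
rests on the planted/true edges ranking far above that tail, not on the
threshold acting as a significance filter. The test suite verifies both
the tail probability and the full null distribution
(Kolmogorov–Smirnov distance ≤ 0.05 over 200 simulated cohorts).

# The synthetic cohort generator

`simulate_bold_cohort()` draws, for subject *s* of group *g*:

1. a target correlation matrix
   `T_s = repair(C0 + b_s ⊙ M_subj + 1[g = cKO] · Δ ⊙ M_grp)`, where
   `C0` is a structured base connectome (homotopic pairs 0.5,
   within-hemisphere 0.2, other inter-hemisphere 0.05), `M_subj` is a
   20-edge subject-identity set shared by **both** groups with
   per-subject zero-mean offsets `b_s` (sd 0.15), and `M_grp` is a
   disjoint 10-edge group set offset by `Δ = 0.3` in cKO only;
2. Gaussian series whose population correlation equals `T_s` exactly
   (Cholesky factorisation), plus independent observation noise
   (sd 0.3 relative to unit-variance signal), which attenuates all
   observed correlations by a common factor.

`repair()` clips eigenvalues at 1e−6 and renormalises the diagonal —
needed because planting arbitrary edge offsets can leave the
positive-definite cone. Identical (spec, seed) inputs reproduce every
artifact bit-identically.

Defaults mirror the target study conditions: 5 control + 7 cKO
subjects, 28 regions (14 per hemisphere, coarse scale), 1002 frames
(3 runs × 334 repetitions) at TR 1.8 s. That `M_subj` is identical in
both groups is precisely what makes the within-group difference
patterns correlate across groups; the disjoint `M_grp` is what the
discriminative network should find. Effect sizes are chosen for test
power (planted effects must be recoverable at desk-scale cohorts), not
fitted to any real effect size, which no public data pin down.

What the generator does **not** emulate: hemodynamic response shape,
physiological (cardiac/respiratory) noise structure, motion artefacts,
scanner drift, spatial autocorrelation of voxel noise, and registration
error. Passing tests therefore demonstrate that the *statistical
machinery* recovers planted structure under Gaussian assumptions — not
that any particular real cohort's numbers would be reproduced.

## Phantoms

`make_atlas_phantom()` builds mirrored left/right labelled regions over
background. Each region is rasterised to its **exact** target voxel
count using a fixed compact fill order inside its cell (voxels sorted
by distance from the cell corner), so the stored truth — count × voxel
volume — is exact by construction and group scalings as small as a few
percent survive rasterisation. Volumes combine: base volume × group
per-region scaling × per-subject global size factor (log-normal,
sd 0.05, the between-animal variation) × per-region jitter (log-normal,
sd 0.02). Phantom grids are desk-scale (tens of voxels per side,
region volumes of order 1 mm³) — volumetric *ratios*, conservation and
test statistics are scale-free, so nothing depends on matching real
brain dimensions.

`simulate_angiogram()` rasterises axis-aligned cylinders at a vessel
intensity over noisy background; a voxel is lumen when its centre lies
within the radius. Half-integer radii (e.g. 3.5) make rasterised widths
match the nominal diameter; integer radii rasterise one voxel wider, a
known discretisation effect the geometry tests account for.

# Volumetry and vascular measures

Regional volume is voxel count × voxel volume on the pre-labelled grid
(registration is out of scope; inputs are assumed atlas-aligned).
Ventricle-flagged regions are excluded from the brain-tissue total and
reported separately, so tissue and CSF effects are never conflated.
Normalisations: by body weight (mm³/g) and by total brain volume
(unitless fraction). Per-region group comparisons use the two-sample
t-test, pooled variance by default, with no multiple-testing correction
by default (matching the uncorrected per-region convention of
small-cohort morphometry); Benjamini–Hochberg sits behind a flag with a
logged note. Conservation is exact at the voxel-count level; mm³ sums
agree to floating-point summation order.

Angiogram segmentation uses a strict `>` comparison (boundary voxels at
exactly the threshold are excluded — a deterministic, documented
convention). Per axis, the maximum-intensity projection is thresholded
and its suprathreshold pixel count × in-plane pixel area gives an
area-valued "vessel volume" correlate; note the 2D MIP measure is
dimensionally an area and is labelled as such, distinct from the 3D
lumen volume. Each (axis, threshold) combination is regressed on brain
volume; the mean ± SD of `R²` across the 9 combinations summarises
vessel–brain coupling.

# Statistics kit

- `two_sample_ttest()` — pooled variance with df = n₁ + n₂ − 2 by
  default; Welch–Satterthwaite behind a flag. A note is emitted when
  the variance ratio exceeds 4 under the pooled mode, because grossly
  unequal group variances are common in cKO morphometry. Identical
  degenerate samples return t = 0, p = 1; unequal constant samples are
  an error.
- `chi_square_2x2()` — Pearson chi-square without continuity
  correction, df = 1; expected counts reported, warning below 5. It
  equals the squared two-proportion z statistic (checked numerically).
- `relative_reduction()` — percent reduction of a treated mean relative
  to control with a delta-method SE for the ratio of independent means:
  `var(m_t/m_c) ≈ var(m_t)/m_c² + m_t²·var(m_c)/m_c⁴`; the p-value
  comes from the t-test on the raw samples. Zero-variance samples give
  the exact reduction with SE 0.
- Type-I calibration of the pooled t at α = 0.05 is verified to
  0.05 ± 0.01 over 10,000 simulations.

# Numerical choices and degenerate inputs

- Eigenvalue floor 1e−6 for correlation repair; repair failure (a
  non-positive diagonal after clipping) names the offending subject.
- Band-pass filtering demeans first, so constants map to ~0 regardless
  of edge transients; series shorter than 3 × order are rejected.
- Global-signal residuals are computed via QR, orthogonal to the global
  mean to ~1e−15; a constant global signal is an error.
- Smoothing with FWHM 0 is the bit-identical identity; kernels truncate
  at 4σ.
- Permutation p-values use the add-one estimator
  `(1 + #{null ≥ obs})/(1 + n_perm)`, never exactly zero.
- All stochastic steps take explicit integer seeds; RNG state is
  restored after each seeded block so library calls never perturb a
  caller's stream.

# Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data at these sizes, chosen as the smallest that make each property
sharp: planted-edge recovery at 20 + 20 subjects × 1000 frames; null
calibration over 200 cohorts of 12 subjects × 378 edges; Type-I
calibration over 10,000 t-tests; phantoms of ~10⁵ voxels. The full
suite completes in well under a minute on one core.

# Known limitations

- Region-level simulation is the default; voxel-level phantoms exercise
  masking/smoothing but paint region series onto voxels rather than
  modelling voxel-level hemodynamics.
- The discriminative network at n = 12 admits a substantial null tail
  (see above); interpretation should lean on effect ranking and
  replication, not the binarisation alone.
- No motion correction or registration: inputs must be pre-aligned to
  the atlas grid.
- Graph-theoretic summaries (modularity, efficiency), partial
  correlations and multivariate classifiers are out of scope.
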