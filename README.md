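# connectodiff

Functional connectome difference-matrix analysis and brain volumetry for
small-cohort rodent MRI studies.

## The problem

A common design in mouse models of neurodevelopmental disease compares a
handful of conditional-knockout (cKO) animals against controls with
resting-state BOLD fMRI and structural MRI. Two questions recur:

1. **Structure** — which brain regions shrink or grow, absolutely, per
   gram of body weight, or as a fraction of total brain volume? Is the
   vasculature affected?
2. **Function** — does the functional connectome (the matrix of Pearson
   correlations between the BOLD signals of all atlas-region pairs)
   carry a *group-specific* signature, and how does it relate to the
   *subject-specific* connectivity fingerprint every animal has?

`connectodiff` implements a complete, testable pipeline for both. Its
core is a difference-matrix procedure: for every pair of subjects the
two connectomes are subtracted edge-wise, giving a *difference matrix*
that characterises what distinguishes that pair. Comparing difference
matrices within a group to those across groups dissociates the
subject-identity pattern (shared across groups) from the pattern that
separates cKO from control. Per edge, the squared point-biserial
correlation `R²` between edge strength and group membership is
thresholded (`R² > 0.2` by default) to yield a signed **discriminative
network**, which is then summarised per macro-region.

Because raw scanner data for such studies are rarely deposited, the
package ships a first-class synthetic-cohort generator: region-level
BOLD series with a planted base connectome, subject-identity edge
offsets and a group edge effect; labelled brain phantoms with planted
volume effects; tube phantoms for angiogram segmentation — each with
exact stored ground truth, so every stage is verifiable end to end.

## Method sketch

For subject *s* with group label *g*, region series are correlated into
a connectome `C_s`. Edges are vectorised in a canonical order (strict
upper triangle, row-major). The pipeline computes:

- difference sets `D_ij = edges(C_i) − edges(C_j)` for all
  control–control, cKO–cKO and control–cKO pairs (10/21/35 pairs at
  n = 5 + 7);
- class similarity: mean `R²` of Pearson correlations between
  difference vectors, with an edge-permutation p-value;
- class patterns: per-edge RMS of difference values, whose
  between-group correlation measures the shared subject fingerprint;
- per-edge discrimination `R² = cor(edge, group)²`, thresholded into
  the discriminative network with sign = direction of the cKO change.

Preprocessing follows the standard resting-state contract:
brain masking, zero-phase Butterworth band-pass 0.008–0.2 Hz,
global-signal regression, Gaussian smoothing to FWHM 0.3 mm.
Volumetry counts atlas voxels (`volume = count × voxel volume`) with
body-weight and total-brain normalisation; angiograms are segmented by
intensity threshold (7000/7500/8000) with per-axis maximum-intensity
projections regressed on brain volume.

## Worked example

```r
library(connectodiff)

spec <- cohort_spec(seed = 21)          # 5 control + 7 cKO, 28 regions,
                                        # 1002 frames at TR 1.8 s
cohort <- simulate_bold_cohort(spec)
conn <- lapply(cohort$series, compute_connectome)

dsets <- difference_matrices(conn)
cp <- class_pattern_correlation(class_pattern(dsets$control_control),
                                class_pattern(dsets$cko_cko))
cp$r
#> [1] 0.7272341

net <- group_discriminative_edges(conn, threshold = 0.2)
mean(cohort$truth$group_edges %in% net$edges$edge)   # recall of planted edges
#> [1] 1
mean(cohort$truth$subject_edges %in% net$edges$edge)
#> [1] 0.25
```

The positive class-pattern correlation (`r = 0.73`) says the edges that
distinguish control mice from one another also distinguish cKO mice
from one another — the shared subject fingerprint. The discriminative
network recovers every planted group edge while touching only a quarter
of the subject-pattern edges: the two patterns dissociate.

A single call runs everything, including phantom volumetry (planted
global cKO shrinkage with an enlarged medulla-analogue region pair) and
vascular measures:

```r
report <- run_pipeline(spec = cohort_spec(n_frames = 400, seed = 7),
                       config = run_config(seed = 7))
print(report)
#> <pipeline_report> 12 subjects, 28 regions
#>   network: 71 edges > R2 0.2 over 28 regions
#>   class patterns: within-control R2 0.168, within-cko R2 0.132, cross-pattern r 0.468
#>   brain volume: 48.71 vs 39.39 mm3 (-19.1%)
#>   vascular: mean R2 0.977 +/- 0.000134
```

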