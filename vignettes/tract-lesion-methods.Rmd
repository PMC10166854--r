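---
title: "Scoring tract lesioning and tremor outcome after MRgFUS thalamotomy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tract lesioning and tremor outcome after MRgFUS thalamotomy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractlesion)
```

## The problem

Magnetic resonance-guided focused ultrasound (MRgFUS) thalamotomy treats
essential tremor by thermally ablating tissue at the ventral intermediate
nucleus (Vim) of the thalamus. The Vim is not visible on structural MRI, so
how much of the intended target — and of the dentatorubrothalamic tract
(DRTT), the cerebellothalamic pathway passing through it — is actually
lesioned varies between patients. This package implements a pipeline that
quantifies that variation and relates it to clinical outcome:

1. decompose the DRTT streamline bundle into anterior, middle and posterior
   sub-bundles by incremental clustering;
2. score each ablation against the streamline bundles (percent transection)
   and against thalamic nuclei segmentations (overlap volume);
3. compute tremor-score changes (CRST and hand tremor scores) and skull
   acoustic-parameter summaries;
4. identify predictors of improvement by two-stage forward-selection linear
   regression with nested-model ANOVA.

Every input has a seeded synthetic generator, so the full pipeline runs and
is tested without patient data.

## Streamline geometry and the MDF distance

A streamline is an ordered polyline of 3D points in scanner millimetres.
All clustering distances operate on streamlines resampled to a fixed number
of points `k` (default 12, the conventional choice for this family of
clustering algorithms; configurable everywhere it matters). Resampling is
piecewise-linear at equal arc-length spacing, iterated to a fixed point: a
single equal-arc pass leaves the output's segment lengths unequal wherever
the polyline bends, because the chords of the resampled polyline are shorter
than the arcs they replace. Iterating until points stop moving (tolerance
1e-9 mm, in practice a handful of passes) makes consecutive gaps equal to
well below the 1% contract and makes the operation idempotent, at the cost
of a sub-jitter-scale shortcut across sharp corners. Endpoints are always
preserved exactly.

The clustering metric is the minimum average direct-flip (MDF) distance:
the mean point-wise Euclidean distance between two `k`-resampled
streamlines, taken both directly and with one streamline reversed, keeping
the minimum. It is symmetric, non-negative, and invariant to the arbitrary
orientation in which a tracking algorithm emits a streamline.

## Cluster decomposition and role labelling

`quickbundles()` is a single-pass incremental clusterer: each streamline, in
stored order, joins the cluster whose running centroid is nearest by MDF if
that distance is strictly below the threshold, else founds a new cluster;
on joining it is flip-aligned to the centroid and the centroid is updated as
the running mean of flip-aligned members. The result is order-dependent by
construction; the package documents this and the tests fix input order.

`select_amp_clusters()` automates the study's manual step of increasing the
threshold until anterior, middle and posterior components appear. The
threshold is swept over a grid (default 2 mm start, 1 mm step, 30 mm cap)
until at least three clusters each hold at least `min_fraction` (default 5%)
of the streamlines — small spurious clusters must not capture a role. The
three largest qualifying clusters are then ranked by the mean
anterior-axis coordinate of their centroid points restricted to a mid-tract
slab (default the middle third of centroid points): rank order is posterior,
middle, anterior. The slab avoids the endpoint regions where the sub-bundles
converge; the anterior axis defaults to +y (RAS) and is configurable. This
replaces visual inspection with a reproducible proxy. If no threshold up to
the cap qualifies, the search fails loudly and reports the cluster-count
trajectory.

`assign_to_centroids()` performs the forced-choice step: every streamline of
a tractogram receives the role of the nearest of the three selected
centroids, so the roles always partition the bundle.

"Most coherent" is not a uniquely defined notion; here the coherence score
of a streamline is its mean MDF distance to all other streamlines of the
bundle, computed exactly (O(N²) at `k = 12`), and `coherence_filter()` keeps
the `n_keep` smallest scores with ties broken by original index. This
definition is deterministic and directly checkable against a brute-force
distance table, which the tests do. Template bundles pool all subjects'
streamlines for a role and keep the 1,000 most coherent.

## Overlap metrics

`streamline_mask_overlap()` counts a streamline as transected if any of its
sample points — resampled at an arc-length step no larger than half the
smallest voxel edge by default — falls in a nonzero voxel of the binary
ablation mask. Point membership uses nearest-voxel rounding with
round-half-away-from-zero on each index, fixed so results are
bit-reproducible; points outside the grid are ignored. Point sampling rather
than exact segment-voxel traversal matches how streamline-ROI inclusion is
conventionally tested, and the transection count is monotone as the step
shrinks (halving the step can only find more hits). The percentage is
100 × transected / total, so 100% means complete transection.

`label_overlap_volumes()` multiplies the hard nuclei segmentation with the
ablation mask: for each label, the overlap volume is the voxel count inside
the mask times the voxel volume (|det| of the affine's 3×3 block). Because a
hard segmentation partitions the grid, the per-label volumes (with
background included) sum exactly to the ablation volume; the tests assert
this identity and the values against a naive triple loop.

Spatial agreement between tractograms and volumes is asserted via explicit
`space_id` text tags, not header forensics — the study never states the grid
on which counting was done, so the package refuses to guess.

## Clinical scores and treatment parameters

CRST parts A (tremor by body region), B (task performance) and C
(disability) are accepted as part totals; the combined score is their sum,
validated against the scale maximum of 160. The hand tremor score (HTS) sums
eight upper-limb items (rest, postural, action tremor, pouring, handwriting,
large and small constrained spirals, constrained straight lines), each
0–4; handwriting is only tested in the dominant hand, so the maxima are 32
(dominant) and 28 (non-dominant). Percent change is signed so that a
positive value is an improvement: 100·(pre − post)/pre; a zero pre-treatment
score makes the change undefined and flags the subject for downstream
exclusion rather than silently propagating. When multiple follow-ups exist,
the latest available one is used, with ties broken deterministically by row
order.

Skull parameters (skull density ratio, skull thickness, inner and outer
skull angle) are measured per transducer element; the arrays must carry
exactly 1,024 values and are summarised by arithmetic mean and sample SD
(denominator n − 1 — the study does not state the denominator; with
n = 1,024 the difference is negligible, but the choice is fixed for
reproducibility).

## Outcome regression

All model variables are z-scored, so reported coefficients are standardized
betas; raw-scale coefficients are emitted alongside, since the study centres
its variables but never states which scale its betas are on. Forward
selection adds, at each step, the candidate whose coefficient t-test p-value
in the model including the already-selected predictors is lowest, provided
it is below alpha (default 0.05), and stops when none qualifies; an empty
selection (intercept-only) is a valid outcome. Ties are broken by larger
|t|, then pool order, making the procedure deterministic. No
multiple-testing correction is applied across responses, matching the
procedure being reimplemented.

The two-stage protocol first selects among patient-specific pre-treatment
variables (age, sex, skull metrics, brain volume, pre-treatment score), then
locks those in and selects among treatment-specific variables (bundle
overlaps, ablation volume, sonication metrics). Baseline and extended models
are compared by the nested F test
F = ((RSS₀ − RSS₁)/Δdf)/(RSS₁/(n − p₁ − 1)); the tests cross-check this
against R's own `anova()` on the same fits. The secondary-lesion exclusion
re-analysis is a row filter on the cohort table, not special-cased logic.

## What the synthetic generators emulate — and what they do not

`gen_bundle()` draws streamlines along a cubic-spline centerline sweeping
from a cerebellar position through the midbrain to the thalamus, with
sub-bundles offset along the anterior axis (default −6/0/+6 mm, 300
streamlines each, 0.5 mm per-point Gaussian jitter). The defaults were fixed
once as the study conditions for all tests: geometric separability is the
goal, not anatomical realism. Real tractograms have curvature-dependent
point density, spurious streamlines, and partial-volume effects that this
generator does not model, so passing clustering tests demonstrate
correctness of the algorithms, not performance on clinical data.

`gen_ablation_mask()` builds exact voxel-centre spheres;
`gen_nuclei_segmentation()` builds Voronoi partitions that satisfy the
hard-segmentation invariant by construction. `gen_treatment_params()` draws
Gaussian element arrays (SDR 0.45 ± 0.1, thickness 7 ± 1.5 mm, angles
12 ± 4 / 15 ± 5°). `gen_cohort()` draws independent predictors with the
population summary statistics of the target cohort (age 75.7 ± 7.2 y,
posterior overlap 25.3 ± 12.1%, ablation volume 11.6 ± 4.8 mm³, n = 31,
nine secondary-lesion subjects) and builds the response from standardized
effects +0.53 (posterior overlap), −0.38 (age), −0.32 (SDR dispersion) plus
Gaussian noise sized so the population R² is 0.55; the response is rescaled
to a percent-change scale (44.8 ± 16.6) and clipped to [−100, 100]. The
response is driven by the stored (post-clipping) predictor columns, so a
noiseless cohort is exactly linear in its own table — the identity the
recovery tests rely on. Predictors are drawn independently, which real
cohorts violate (age and brain volume correlate, overlaps correlate with
ablation volume); with correlated predictors forward selection would behave
less cleanly than these tests show.

At n = 31 with these effect sizes, the weakest effect (|β| = 0.32,
t ≈ 2.5 at ~27 df) has roughly 60–70% power at alpha 0.05, so any single
replicate frequently fails to retain all three true predictors even though
each is retained in the majority of replicates and the retained coefficients
are nearly unbiased. This is a property of the study's own scale, and the
test suite reflects it rather than inflating the sample.

## Numerical choices and degenerate inputs

* Resampling: piecewise-linear, no spline smoothing — deterministic and
  checkable against a dense arc-length table; iterated to a fixed point as
  described above. A zero-length streamline resamples to repeated points.
* TCK I/O: the single supported dialect is float32 little-endian,
  NaN-delimited, Inf-terminated, magic `mrtrix tracks`; truncation errors
  name the byte offset. NIfTI affines are written via the sform only, since
  the quaternion (qform) route does not round-trip anisotropic or sheared
  affines exactly. Voxel indices are 0-based and map to voxel centres.
* Displacement fields are applied after the affine by trilinear
  interpolation; points outside the field's domain are an error naming the
  streamline, never an extrapolation — silent extrapolation would corrupt
  overlap scores.
* Forward selection skips candidates whose fit is degenerate (non-finite
  p-value, e.g. after a perfect fit) instead of comparing against NaN.
* All generators are pure functions of their arguments and seed; the
  multi-subject dataset writer derives per-subject, per-stage seeds
  additively (`seed + 1000·subject + stage`) so they stay within 32-bit
  range.

## Problem sizes used by the test suite

The suite exercises the coherence filter at the study scale (3,000
streamlines reduced to 1,000), clustering on 900-streamline three-sub-bundle
phantoms and a 10-subject pooled set, regression recovery on 200 seeded
31-subject cohorts, null-ANOVA calibration on 500 seeded replicates, and
brute-force oracles (pairwise MDF tables, triple-loop voxel counts, normal
equations) on small instances where exhaustive computation is exact. These
sizes were chosen to match the study conditions where the study fixes them
and to keep oracles exact elsewhere.

## Known limitations

* Clustering is order-dependent (inherent to the single-pass algorithm);
  reproducibility therefore requires fixed input order, which all pipeline
  stages maintain.
* Transection uses point sampling, not exact 3D segment-voxel traversal; an
  exact traversal would be a drop-in extension.
* The package applies spatial transforms but never estimates them;
  registration quality is upstream of everything here.
* Tractography itself (FOD estimation, probabilistic tracking) is out of
  scope: tractograms are inputs.
* Whether the study's printed betas are standardized or raw-on-centred
  coefficients is not stated; both are reported here.
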