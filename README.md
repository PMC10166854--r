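# tractlesion

Quantifying how a focused-ultrasound thalamotomy lesion intersects the
dentatorubrothalamic tract (DRTT), and what that predicts about tremor
outcome.

MRgFUS thalamotomy ablates tissue at the ventral intermediate nucleus (Vim)
of the thalamus to suppress essential tremor. The Vim is invisible on
structural MRI, and the DRTT — the cerebellothalamic pathway through it —
takes several distinguishable paths through the thalamus. This package is
for neuroimaging analysts who have, per subject, a tractogram of the DRTT,
an ablation-core segmentation, thalamic nuclei segmentations, tremor rating
scores and transducer-array skull parameters, and want to know: *which part
of the tract was lesioned, by how much, and does that explain who improved?*

## Methods at the core

* **Streamline clustering.** Streamlines are resampled to *k* points (default
  12) and compared by the minimum average direct-flip distance
  MDF(a, b) = min( mean‖aᵢ − bᵢ‖, mean‖aᵢ − b₍ₖ₊₁₋ᵢ₎‖ ).
  A single-pass incremental clusterer (`quickbundles()`) merges each
  streamline into the nearest running centroid under a threshold;
  `select_amp_clusters()` sweeps the threshold upward until three clusters of
  at least 5% of streamlines each emerge and labels them
  anterior/middle/posterior by the anterior coordinate of their mid-tract
  centroids. `coherence_filter()` keeps the *n* streamlines with the smallest
  mean MDF to all others (e.g. 3,000 → 1,000).
* **Overlap scoring.** Transection percentage = 100 × (streamlines with any
  arc-length sample in a nonzero mask voxel) / (bundle size); per-nucleus
  overlap volume = voxels of each label inside the mask × voxel volume.
* **Clinical scores.** CRST parts A/B/C with combined maximum 160; hand
  tremor scores out of 32 (dominant) / 28 (non-dominant); signed percent
  change 100·(pre − post)/pre, positive = improvement; per-element skull
  parameters (1,024 transducer elements) summarised as mean and sample SD.
* **Outcome regression.** Two-stage forward selection on standardized
  variables: patient-specific predictors first, then treatment-specific
  predictors with stage-1 locked in; entry by lowest coefficient p < 0.05;
  baseline vs extended compared by nested F test on residual sums of squares.
* **Synthetic generators** for every input (bundles with sub-bundle
  structure, spherical ablation masks, Voronoi hard segmentations, skull
  parameter arrays, outcome cohorts with known standardized effects), all
  pure functions of a seed.

File formats: MRtrix TCK tractograms, NIfTI-1 label volumes and displacement
fields, whitespace-delimited 4×4 affines, CSV clinical/treatment tables.

## Worked example

```r
library(tractlesion)

gb  <- gen_bundle(seed = 42)              # 900 streamlines, 3 sub-bundles
dec <- select_amp_clusters(gb$tractogram) # adaptive threshold search
#> cluster_decomposition: 3 clusters at threshold 2.00 mm (sizes: 300, 300, 300)
#>   roles: posterior=cluster 1, middle=cluster 2, anterior=cluster 3

roles <- assign_to_centroids(gb$tractogram, amp_centroids(dec))
mean(roles == gb$labels)                  # generative-label agreement: 1.0

aff <- diag(4); aff[1:3, 4] <- c(-16, -60, -40)
mask <- gen_ablation_mask(c(13, -18, 3), 3, c(64, 64, 64), aff)
for (r in c("anterior", "middle", "posterior")) {
  sel <- tractogram(gb$tractogram$streamlines[roles == r], "native")
  print(streamline_mask_overlap(sel, mask, bundle_name = r, check_space = FALSE))
}
#> anterior: 0/300 streamlines transected (0.0%)
#> middle: 300/300 streamlines transected (100.0%)
#> posterior: 0/300 streamlines transected (0.0%)

g   <- gen_cohort(seed = 42)              # 31 subjects, known effects
res <- two_stage_select(g$table, "crst_t_change",
                        g$patient_pool, g$treatment_pool)
print(res$extended)
#> fitted_model: crst_t_change ~ pdrtt_overlap  (n=31, R^2=0.206)
#>   pdrtt_overlap            beta= 0.454  p=0.01023
print(res$comparison)
#> model_comparison: F(1,29) = 7.546, p = 0.01023
```

A 3 mm ablation centred on the middle sub-bundle transects it completely and
misses its neighbours 6 mm away — the contrast the role decomposition
exists to expose. In the cohort replicate shown, forward selection at n = 31
retains the posterior-overlap effect (generative β = +0.53) with a positive
coefficient; at this sample size the weaker generative effects (age −0.38,
SDR dispersion −0.32) do not reach the 0.05 entry threshold in every
replicate.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write their tables under `results/`:

1. `01_simulate.R` — 10-subject dataset (tractograms, masks, segmentations,
   clinical and treatment tables) under `scratch/study/`.
2. `02_cluster.R` — pooled adaptive clustering, role labelling, per-role
   template bundles, agreement with generative labels.
3. `03_overlap.R` — per-subject transection percentages and per-nucleus
   overlap volumes, plus native-vs-template overlap correlations.
4. `04_outcomes.R` — tremor score changes and skull-parameter summaries.
5. `05_regression.R` — two-stage forward selection on a 31-subject cohort
   with the study's effect structure, with the secondary-lesion exclusion
   rerun.

Run them in order with `Rscript analysis/01_simulate.R` etc.

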