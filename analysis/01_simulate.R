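#!/usr/bin/env Rscript
# Stage 1: simulate the study's raw inputs.
#
# Writes a multi-subject synthetic dataset — per subject a native tractogram
# with anterior/middle/posterior sub-bundle structure, a spherical ablation
# mask near the thalamic end of the tract, a hard nuclei segmentation,
# pre/post clinical records and per-element skull parameters. Imaging data
# go to scratch/ (regenerable); the run manifest goes to results/.

suppressPackageStartupMessages(library(tractlesion))

seed <- 2026L
data_dir <- "scratch/study"
dir.create("results", showWarnings = FALSE)

cfg <- gen_study_dataset(data_dir, n_subjects = 10L, seed = seed,
                         n_streamlines = 300L, mask_radius = 3)
saveRDS(cfg, file.path(data_dir, "config.rds"))

n_stream <- vapply(cfg$subjects, function(s)
  length(read_tractogram(s$native_tck)), integer(1))
cat(sprintf("simulated %d subjects under %s\n", length(cfg$subjects), data_dir))
cat(sprintf("  native streamlines per subject: %s\n",
            paste(unique(n_stream), collapse = ", ")))
cat(sprintf("  clinical records: %s\n  treatment arrays: %s\n",
            cfg$clinical_csv, cfg$treatment_csv))
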