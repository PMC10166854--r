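#!/usr/bin/env Rscript
# Stage 3: score lesion-tract and lesion-nucleus overlap per subject.
#
# For each subject: percentage of streamlines transected by the ablation
# mask for the native tract and the three role bundles, and the overlap
# volume of the mask with each segmented nucleus. Also reports the
# correlation between native and per-role overlap across subjects.

suppressPackageStartupMessages(library(tractlesion))

data_dir <- "scratch/study"
cfg <- readRDS(file.path(data_dir, "config.rds"))
cfg$out_dir <- "results/overlap"

rep <- run_overlap_pipeline(cfg)
stopifnot(rep$n_failed == 0L)
cat(sprintf("scored %d subjects; overlap tables under %s\n",
            length(cfg$subjects), cfg$out_dir))

summ <- rep$summary
for (b in c("native", "anterior", "middle", "posterior"))
  cat(sprintf("  %-9s overlap: %5.1f%% +/- %4.1f%%\n", b,
              mean(summ[[paste0(b, "_overlap")]]),
              sd(summ[[paste0(b, "_overlap")]])))
cat(sprintf("  ablation volume: %.1f +/- %.1f mm^3\n",
            mean(summ$ablation_volume), sd(summ$ablation_volume)))

for (b in c("anterior", "middle", "posterior")) {
  ct <- try(pearson(summ$native_overlap, summ[[paste0(b, "_overlap")]]),
            silent = TRUE)
  if (!inherits(ct, "try-error"))
    cat(sprintf("  r(native, %s) = %.3f (R^2 = %.3f, p = %.3f, n = %d)\n",
                b, ct$r, ct$r_squared, ct$p, ct$n))
}
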