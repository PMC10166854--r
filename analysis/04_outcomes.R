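#!/usr/bin/env Rscript
# Stage 4: tremor score changes and skull-parameter summaries.
#
# Pairs each subject's pre-treatment scores with the latest follow-up,
# computes signed percent changes (positive = improvement) for the three
# CRST parts, the combined CRST and both hands' HTS, and summarises the
# per-element skull parameters as mean and SD over the 1,024 transducer
# elements.

suppressPackageStartupMessages(library(tractlesion))

data_dir <- "scratch/study"
cfg <- readRDS(file.path(data_dir, "config.rds"))

records <- read_clinical_csv(cfg$clinical_csv)
changes <- score_changes(records)
write.csv(changes, "results/score_changes.csv", row.names = FALSE)
cat(sprintf("score changes for %d subjects -> results/score_changes.csv\n",
            nrow(changes)))
for (col in c("crst_a_change", "crst_b_change", "crst_c_change",
              "crst_t_change", "hts_d_change", "hts_nd_change"))
  cat(sprintf("  %-14s %6.1f%% +/- %5.1f%%\n", col,
              mean(changes[[col]], na.rm = TRUE),
              sd(changes[[col]], na.rm = TRUE)))

treatments <- read_treatment_csv(cfg$treatment_csv)
summ <- do.call(rbind, lapply(names(treatments), function(id) {
  s <- treatment_summary(treatments[[id]])
  s$subject_id <- id
  s
}))
write.csv(summ, "results/treatment_summaries.csv", row.names = FALSE)
cat(sprintf("skull-parameter summaries for %d subjects -> results/treatment_summaries.csv\n",
            length(treatments)))
agg <- aggregate(cbind(mean, sd) ~ parameter, summ, mean)
print(agg, row.names = FALSE)
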