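#!/usr/bin/env Rscript
# Stage 5: predictors of tremor improvement by two-stage forward selection.
#
# Runs the outcome regression on a synthetic 31-subject cohort generated
# with the study's effect structure (posterior-bundle overlap +0.53, age
# -0.38, SDR dispersion -0.32 on the standardized scale, population R^2
# 0.55): stage 1 selects among patient-specific pre-treatment variables,
# stage 2 adds treatment-specific variables with stage-1 predictors locked
# in, and the models are compared by nested ANOVA. The secondary-lesion
# exclusion rerun drops the 9 flagged subjects.

suppressPackageStartupMessages(library(tractlesion))

seed <- 2026L
g <- gen_cohort(seed = seed)
dir.create("results", showWarnings = FALSE)
cohort_csv <- "results/cohort_table_synthetic.csv"
write.csv(g$table, cohort_csv, row.names = FALSE)

cfg <- list(cohort_csv = cohort_csv,
            out_dir = "results/models",
            responses = "crst_t_change",
            patient_pool = g$patient_pool,
            treatment_pool = g$treatment_pool,
            exclude_secondary = TRUE)
res <- run_cohort_analysis(cfg)

r <- res$crst_t_change
cat("baseline (patient-specific) model:\n"); print(r$baseline)
cat("extended (plus treatment-specific) model:\n"); print(r$extended)
cat("nested comparison: "); print(r$comparison)
cat(sprintf("generative effects: %s (population R^2 = 0.55)\n",
            paste(sprintf("%s=%+.2f", names(g$betas), g$betas),
                  collapse = ", ")))
cat("model report: results/models/model_crst_t_change.json\n")
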