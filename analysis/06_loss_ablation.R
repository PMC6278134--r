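#!/usr/bin/env Rscript
# Stage 6: loss-function ablation.
#
# Compares the imbalance-penalizing objective against plain cross-entropy
# across the whole experimental grid (both single-input models, and the
# dual model under both losses x both transfer sources), reporting
# validation and test AUC with stratified bootstrap CIs.

suppressPackageStartupMessages(library(strokehr))

splits <- readRDS("scratch/analysis_splits.rds")
models <- readRDS("scratch/analysis_models.rds")

report <- loss_ablation(models, splits, replicates = 1000L, seed = 1)
print(report, digits = 3)
write.csv(report, "results/analysis/loss_ablation.csv", row.names = FALSE)
cat("wrote results/analysis/loss_ablation.csv\n")
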