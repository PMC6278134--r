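#!/usr/bin/env Rscript
# Stage 3: encode the cohort into model inputs.
#
# Trains the ICD-10 autoencoder on the population's code vocabulary, fits
# the scaler and gender-mean imputation statistics on the training split
# only, and assembles the padded diagnosis/exam/dual instance sets per
# split. Instance arrays are cached under scratch/ (they are large and
# reproducible); text artifacts go under results/.

suppressPackageStartupMessages(library(strokehr))

data_seed <- 101
pop <- read_population("results/analysis/data")
cohort_tab <- read_cohort("results/analysis/cohort.csv")

vocab <- code_vocabulary(pop$diagnoses$icd10_code)
cat("code vocabulary:", length(vocab), "truncated codes\n")
embedder <- train_autoencoder(vocab, dim = 32, seed = data_seed)
cat("autoencoder reconstruction accuracy:",
    embedder$reconstruction_accuracy, "after", embedder$epochs_run, "epochs\n")
write_autoencoder(embedder, "results/analysis/embedder")

train_ids <- unique(c(cohort_tab$case_id[cohort_tab$split == "train"],
                      cohort_tab$control_id_1[cohort_tab$split == "train"],
                      cohort_tab$control_id_2[cohort_tab$split == "train"]))
stats <- fit_scaler(pop, train_ids)
write_scaler(stats, "results/analysis/scaler_stats.yaml")

splits <- featurize_cohort(pop, cohort_tab, embedder, stats)
dir.create("scratch", showWarnings = FALSE)
saveRDS(splits, "scratch/analysis_splits.rds")

counts <- do.call(rbind, lapply(names(splits), function(sp) {
  s <- splits[[sp]]
  data.frame(split = sp,
             diagnosis_instances = length(s$diagnosis$y),
             diagnosis_positive = sum(s$diagnosis$y),
             exam_instances = length(s$exam$y),
             exam_positive = sum(s$exam$y),
             dual_instances = length(s$dual$y),
             dual_positive = sum(s$dual$y))
}))
print(counts)
write.csv(counts, "results/analysis/instance_counts.csv", row.names = FALSE)
cat("wrote instance sets to scratch/analysis_splits.rds\n")
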