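#!/usr/bin/env Rscript
# Stage 4: train the experimental grid of predictors.
#
# Eight configurations: the recurrent diagnosis model and the dense exam
# model each under the imbalance loss and plain cross-entropy, and the
# dual-input model under both losses x both weight-transfer sources
# (branches trained with the custom loss vs with CE). Checkpoints are
# selected by validation F1. Model objects are cached under scratch/; the
# training summaries go to results/.

suppressPackageStartupMessages(library(strokehr))

splits <- readRDS("scratch/analysis_splits.rds")
train_seed <- 1
sargs <- list(recurrent_width = 32L, td_width = 16L,
              dense_widths = c(32L, 16L), fusion_width = 16L)
epochs_single <- 25L
epochs_dual <- 12L

spec_for <- function(kind) do.call(model_spec, c(list(kind), sargs))
fit <- function(kind, train, val, loss, epochs) {
  train_model(build_model(spec_for(kind), seed = train_seed), train, val,
              train_config(epochs = epochs, seed = train_seed, loss = loss))
}

models <- list()
for (loss_name in c("custom", "ce")) {
  loss <- if (loss_name == "custom") loss_config() else "ce"
  cat("training model1 (", loss_name, ") ...\n", sep = "")
  models[[paste0("model1_", loss_name)]] <-
    fit("diagnosis_rnn", splits$train$diagnosis, splits$validation$diagnosis,
        loss, epochs_single)
  cat("training model2 (", loss_name, ") ...\n", sep = "")
  models[[paste0("model2_", loss_name)]] <-
    fit("exam_dense", splits$train$exam, splits$validation$exam,
        loss, epochs_single)
}
for (loss_name in c("custom", "ce")) {
  for (src in c("custom", "ce")) {
    cat("training model3 (", loss_name, ", transfer from ", src, ") ...\n",
        sep = "")
    m3 <- build_model(spec_for("dual_input"), seed = train_seed)
    m3 <- transfer_weights(m3, models[[paste0("model1_", src)]],
                           models[[paste0("model2_", src)]])
    loss <- if (loss_name == "custom") loss_config() else "ce"
    models[[paste0("model3_", loss_name, "_from_", src)]] <-
      train_model(m3, splits$train$dual, splits$validation$dual,
                  train_config(epochs = epochs_dual, seed = train_seed,
                               loss = loss))
  }
}

saveRDS(models, "scratch/analysis_models.rds")
summary <- do.call(rbind, lapply(names(models), function(nm)
  data.frame(configuration = nm, best_epoch = models[[nm]]$best_epoch,
             validation_f1 = models[[nm]]$best_f1)))
print(summary)
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)
write.csv(summary, "results/analysis/training_summary.csv", row.names = FALSE)
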