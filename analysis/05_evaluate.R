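#!/usr/bin/env Rscript
# Stage 5: ROC evaluation of the primary (custom-loss) models.
#
# All three models are scored on the common dual test set -- the diagnosis
# model on its diagnosis half, the exam model on its exam half, the dual
# model on both -- so the comparison is over identical anchors and labels.
# Their own-set validation/test AUCs are reported alongside.

suppressPackageStartupMessages(library(strokehr))

splits <- readRDS("scratch/analysis_splits.rds")
models <- readRDS("scratch/analysis_models.rds")
replicates <- 1000L

half <- function(du, which) {
  out <- if (which == "d") list(x = du$x_d, mask = du$mask_d, y = du$y)
         else list(x = du$x_e, mask = du$mask_e, y = du$y)
  class(out) <- "instance_set"
  out
}

rows <- list()
for (sp in c("validation", "test")) {
  du <- splits[[sp]]$dual
  inputs <- list(model1_custom = half(du, "d"),
                 model2_custom = half(du, "e"),
                 model3_custom_from_custom = du)
  for (nm in names(inputs)) {
    sc <- predict_scores(models[[nm]], inputs[[nm]])
    roc <- roc_and_auc(sc, du$y)
    roc$ci <- bootstrap_auc_ci(sc, du$y, replicates, seed = 1)
    write_roc(roc, sprintf("results/analysis/roc_%s_%s.csv", nm, sp))
    rows[[paste(nm, sp)]] <- data.frame(
      model = nm, split = sp, auc = roc$auc,
      ci_lower = roc$ci[1], ci_upper = roc$ci[2],
      f1 = suppressMessages(f1_score(sc, du$y)))
  }
}
metrics <- do.call(rbind, rows)
rownames(metrics) <- NULL
print(metrics, digits = 3)
write.csv(metrics, "results/analysis/metrics.csv", row.names = FALSE)
cat("wrote results/analysis/metrics.csv\n")
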