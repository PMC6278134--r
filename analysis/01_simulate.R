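#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic hospital population.
#
# Generates the default study population (planted stroke hazard split
# between risk codes and drifting exam metrics), writes the three-table CSV
# layout plus the generator config, and reports headline counts. Downstream
# stages reload the CSVs, so this stage is the single source of the data.

suppressPackageStartupMessages(library(strokehr))

n_patients <- 2000          # analysis scale; see the methods vignette
data_seed <- 101
out_data <- "results/analysis/data"
dir.create(out_data, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(n_patients = n_patients, seed = data_seed)
pop <- generate_population(cfg)
pop <- inject_stroke_events(pop, cfg)

write_population(pop, out_data)
write_generator_config(cfg, file.path(out_data, "generator_config.yaml"))

n_stroke <- length(strokehr:::stroke_patients(pop))
cat("population:", nrow(pop$patients), "patients,",
    nrow(pop$diagnoses), "diagnoses,", nrow(pop$exams), "exam values\n")
cat("patients with a stroke diagnosis:", n_stroke,
    sprintf("(%.1f%%)\n", 100 * n_stroke / nrow(pop$patients)))
cat("diagnoses per patient (median):",
    median(table(pop$diagnoses$patient_id)), "\n")
cat("wrote", out_data, "\n")
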