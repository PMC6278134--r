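#!/usr/bin/env Rscript
# Stage 2: build the matched case/control cohort.
#
# Cases: first stroke diagnosis in 2001-2015 at ages 45-95 with at least one
# diagnosis and one exam at least a day earlier. Controls: two per case,
# same birth year and gender, records strictly before and after the index
# date, stroke-free. Cases are split 70/15/15 and controls inherit their
# case's split.

suppressPackageStartupMessages(library(strokehr))

data_seed <- 101
pop <- read_population("results/analysis/data")

cases <- select_cases(pop)
cat("eligible cases:", nrow(cases), "\n")

cohort <- match_controls(cases, pop, seed = data_seed)
cat("matched cases:", nrow(cohort$cases),
    "; excluded for lack of 2 controls:", length(cohort$excluded_cases), "\n")

split <- split_cohort(cohort, seed = data_seed)
print(table(split$split, split$role))

write_cohort(cohort, split, "results/analysis/cohort.csv")
cat("wrote results/analysis/cohort.csv\n")
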