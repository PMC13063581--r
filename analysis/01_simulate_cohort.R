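#!/usr/bin/env Rscript
# Stage 1: simulate a raw survey cohort with the default generator
# settings (marginals mirroring the published baseline table, a logistic
# outcome model for current PrEP use, stratum-specific reason
# probabilities and per-field missingness) and write it as CSV.

suppressMessages(library(prepbarriers))

seed <- 20260923L
cfg <- cohort_config(3500, seed = seed)
rec <- inject_missingness(generate_cohort(cfg), cfg$missing_rate, seed = cfg$seed)

dir.create("results", showWarnings = FALSE)
write_cohort_csv(rec, "results/cohort_raw.csv")
write_cohort_config(cfg, "results/cohort_config.yaml")

cat("simulated", nrow(rec), "records ->", "results/cohort_raw.csv\n")
print(table(rec$prep_status))
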