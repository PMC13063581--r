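#!/usr/bin/env Rscript
# Stage 3: derive the grouped covariates (age bands, equivalised-income
# bands via the square-root scale, HIV-specialist density bands) and
# encode the reference-coded one-hot design matrix with missing values
# as their own category.

suppressMessages(library(prepbarriers))

rec <- read_cohort_csv("results/cohort_selected.csv")
an <- prepare_covariates(rec)
dm <- build_design_matrix(an)
print(dm)

utils::write.csv(cbind(prep_user = dm$y, dm$x),
                 "results/design_matrix.csv", row.names = FALSE)
jsonlite::write_json(list(meta = dm$meta, reference = as.list(dm$reference),
                          missing_mode = dm$missing_mode),
                     "results/design_metadata.json",
                     dataframe = "rows", auto_unbox = TRUE)
cat("reference categories:\n")
print(dm$reference)
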