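#!/usr/bin/env Rscript
# Stage 4: tune the elastic net (15-fold stratified repeated CV over the
# mixing grid, one-SE elbow strength per mixing), fit the per-mixing
# candidates and choose the final model by sparsity then AIC.

suppressMessages(library(prepbarriers))

rec <- read_cohort_csv("results/cohort_selected.csv")
dm <- build_design_matrix(prepare_covariates(rec))

sel <- tune_and_choose(dm, tuning_config(n_repeats = 2, seed = 20260923L))
utils::write.csv(sel$grid, "results/tuning_grid.csv", row.names = FALSE)

chosen <- sel$chosen
print(chosen)
cat("\ncandidates (one per mixing):\n")
for (cand in sel$candidates) {
  cat(sprintf("  mixing %.1f  strength %8.5f  nnz %2d  AIC %.1f\n",
              cand$mixing, cand$strength, cand$n_nonzero, cand$aic))
}
jsonlite::write_json(
  list(mixing = chosen$mixing, strength = chosen$strength,
       intercept = chosen$intercept, n_nonzero = chosen$n_nonzero,
       aic = chosen$aic, beta = as.list(chosen$beta)),
  "results/chosen_model.json", auto_unbox = TRUE, digits = NA)
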