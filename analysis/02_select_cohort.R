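#!/usr/bin/env Rscript
# Stage 2: apply the participant-selection flow (completion, cis-male,
# PrEP status, repeat participation, HIV-negative confirmation,
# PrEP-indication criteria) and keep the auditable ledger.

suppressMessages(library(prepbarriers))

rec <- recode_missing(read_cohort_csv("results/cohort_raw.csv"))
cohort <- apply_selection_flow(rec)
print(cohort)

write_cohort_csv(cohort$records, "results/cohort_selected.csv")
jsonlite::write_json(cohort$ledger, "results/selection_ledger.json",
                     dataframe = "rows", auto_unbox = TRUE)
tab <- table(cohort$records$role, cohort$records$indication_subgroup)
cat("\nindication subgroups by role:\n")
print(tab)
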