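#!/usr/bin/env Rscript
## Baseline characteristics (shock vs non-shock) and clinical outcomes
## tables for the phenotyped synthetic cohort: demographics, community
## onset, comorbidities and treatments; then deduplicated in-hospital
## mortality, deaths per 1,000 inpatients, hospital and ICU LOS, ICU
## admission.

suppressMessages(library(sepsisclaims))
library(data.table)

episodes <- fread("results/episodes.csv")
diagnoses <- fread("results/synthetic_claims/diagnoses.csv")

t1 <- build_table1(episodes, diagnoses)
write_table(t1, "results/table1_characteristics.csv")
cat("Characteristics (shock vs non-shock):\n")
print(t1)

t2 <- build_table2(episodes)
write_table(t2, "results/table2_outcomes.csv")
cat("\nOutcomes:\n")
print(t2)
cat("\nWrote results/table1_characteristics.csv, results/table2_outcomes.csv\n")
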