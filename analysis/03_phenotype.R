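#!/usr/bin/env Rscript
## Apply the operational case definitions to the simulated claims: presumed
## serious infection (blood culture + new IV antibiotic course >= 4
## consecutive days within ±2 days, or death before completion), acute organ
## dysfunction, vasopressor-defined shock, 48-h community onset. Scores the
## verdicts against generator ground truth — the near-miss negatives must
## all classify negative.

suppressMessages(library(sepsisclaims))

claims <- read_claims("results/synthetic_claims/admissions.csv",
                      "results/synthetic_claims/diagnoses.csv",
                      "results/synthetic_claims/events.csv")
claims$admissions <- filter_cohort(claims$admissions)
claims$truth <- data.table::fread("results/synthetic_claims/ground_truth.csv")

episodes <- classify_admissions(claims)
write_table(episodes, "results/episodes.csv")
cat(sprintf("phenotyped %d admissions: %d sepsis (%d shock, %d community onset)\n",
            nrow(episodes), sum(episodes$is_sepsis), sum(episodes$is_shock),
            sum(episodes$is_community_onset)))

acc <- phenotype_accuracy(claims)
cat(sprintf("vs ground truth: sensitivity %.3f, specificity %.3f\n",
            acc$sensitivity, acc$specificity))
cat("near-miss false positives:\n")
print(acc$near_miss_fp)
cat("Wrote results/episodes.csv\n")
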