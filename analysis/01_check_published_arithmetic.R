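#!/usr/bin/env Rscript
## Recompute the published nationwide surveillance ratios from the packaged
## printed counts: shock share among sepsis, sepsis prevalence among all
## inpatient admissions, deduplicated in-hospital mortality, deaths per
## 1,000 inpatients (overall / shock / non-shock), ICU admission, and the
## shock-group characteristics percentages. Every value is recomputed by
## the package's proportion and rate operations, not transcribed.

suppressMessages(library(sepsisclaims))
dir.create("results", showWarnings = FALSE)

arith <- check_arithmetic()
write_table(arith, "results/published_arithmetic.csv")
cat("Published surveillance ratios recomputed from printed counts:\n\n")
print(arith[, c("quantity", "numerator", "denominator", "display")])
cat("\nShock deaths/1,000 + non-shock deaths/1,000 =",
    sprintf("%.2f", arith$value[arith$quantity == "deaths_per_1000_shock"] +
              arith$value[arith$quantity == "deaths_per_1000_nonshock"]),
    "(overall:", sprintf("%.2f)", arith$value[
      arith$quantity == "deaths_per_1000_overall"]), "\n")
cat("Wrote results/published_arithmetic.csv\n")
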