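#!/usr/bin/env Rscript
## Yearly trends 2010-2020 with the matching tests: Cochran-Armitage for
## in-hospital mortality and sepsis proportion among inpatients, linear
## regression for deaths per 1,000 inpatients and mean LOS (overall and
## stratified by survival), plus age-band / sex / ICU x shock subgroup
## mortality trends.

suppressMessages(library(sepsisclaims))
library(data.table)

episodes <- fread("results/episodes.csv")
tr <- build_trends(episodes, analysis_plan())
for (nm in setdiff(names(tr), "tests"))
  write_table(tr[[nm]], file.path("results", paste0("trend_", nm, ".csv")))
write_table(tr$tests, "results/trend_tests.csv")

cat("Trend tests on the synthetic cohort:\n")
print(tr$tests)
m <- tr$mortality
cat("\nShock mortality endpoints: ",
    sprintf("%.1f%% (2010) -> %.1f%% (2020)\n",
            m[group == "shock" & year == min(year), value],
            m[group == "shock" & year == max(year), value]))
cat("Wrote results/trend_*.csv and results/trend_tests.csv\n")
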