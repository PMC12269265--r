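small_bundle <- function(seed = 17) {
  run_pipeline(sim_config(n_admissions_per_year = 600, years = 2010:2013,
                          seed = seed))
}

test_that("characteristics table partitions shock and non-shock", {
  b <- small_bundle()
  n_row <- b$table1[b$table1$variable == "n"]
  expect_equal(as.integer(n_row$shock) + as.integer(n_row$nonshock),
               as.integer(n_row$overall))
  expect_equal(as.integer(n_row$overall), sum(b$episodes$is_sepsis))
})

test_that("characteristics percentages match hand computation on a fixture cohort", {
  sim <- simulate_claims(sim_config(n_admissions_per_year = 800,
                                    years = 2011:2012, seed = 23))
  ep <- classify_admissions(sim)
  t1 <- build_table1(ep, sim$diagnoses)
  sep <- ep[ep$is_sepsis == TRUE]
  fem <- t1[t1$variable == "female"]
  k <- sum(sep$sex == "female")
  expect_equal(fem$overall, sprintf("%d (%.1f)", k, 100 * k / nrow(sep)))
  co <- t1[t1$variable == "community_onset"]
  k <- sum(sep$is_community_onset)
  expect_equal(co$overall, sprintf("%d (%.1f)", k, 100 * k / nrow(sep)))
})

test_that("an all-male cohort reports a zero female row", {
  sim <- simulate_claims(sim_config(n_admissions_per_year = 400,
                                    years = 2011:2012, p_male = 1,
                                    seed = 5))
  ep <- classify_admissions(sim)
  t1 <- build_table1(ep, sim$diagnoses)
  fem <- t1[t1$variable == "female"]
  expect_match(fem$overall, "^0 \\(0\\.0\\)$")
})

test_that("trend tables conserve counts across subgroup partitions", {
  b <- small_bundle()
  tr <- b$trends
  ## shock + nonshock yearly totals equal deduplicated sepsis patients
  mort <- tr$mortality
  dd <- deduplicate(b$episodes)
  expect_equal(sum(mort$total), nrow(dd))
  ## age bands partition the deduplicated cohort
  if (!is.null(tr$mortality_by_age))
    expect_equal(sum(tr$mortality_by_age$total), nrow(dd))
  ## sexes partition it too
  expect_equal(sum(tr$mortality_by_sex$total), nrow(dd))
  ## sepsis proportion uses admission-level counts
  expect_equal(sum(tr$sepsis_proportion$events), sum(b$episodes$is_sepsis))
})

test_that("a declining-mortality generator yields a detected decreasing trend", {
  ## ground-truth episodes at a size where the trend is unambiguous
  sim <- simulate_claims(sim_config(n_admissions_per_year = 20000, seed = 61),
                         events = FALSE)
  ep <- episodes_from_truth(sim)
  tr <- build_trends(ep, analysis_plan(subgroup_axes = "sex"))
  t_ns <- tr$tests[tr$tests$outcome == "inhospital_mortality" &
                     tr$tests$group == "nonshock"]
  expect_equal(t_ns$direction, "decreasing")
  expect_lt(t_ns$p_value, 0.05)
})

test_that("pipeline bundles are reproducible and stage failures are named", {
  b1 <- run_pipeline(sim_config(n_admissions_per_year = 300,
                                years = 2010:2012, seed = 7))
  b2 <- run_pipeline(sim_config(n_admissions_per_year = 300,
                                years = 2010:2012, seed = 7))
  expect_identical(b1$table1, b2$table1)
  expect_identical(b1$table2, b2$table2)
  expect_identical(b1$adjusted_or, b2$adjusted_or)
  expect_identical(b1$manifest$config_hash, b2$manifest$config_hash)
  d1 <- file.path(tempdir(), "bd1"); d2 <- file.path(tempdir(), "bd2")
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  ## missing events file fails in the named stage
  dir.create(tp <- file.path(tempdir(), "brokenpipe"), showWarnings = FALSE)
  write_table(b1$episodes[0], file.path(tp, "admissions.csv"))
  expect_error(run_pipeline(tp), "stage 'read'")
})

test_that("adjusted model reports the per-year OR by stratum", {
  sim <- simulate_claims(sim_config(n_admissions_per_year = 5000, seed = 13),
                         events = FALSE)
  ep <- episodes_from_truth(sim)
  ## no diagnoses in cohort mode: comorbidity flags all-false are dropped
  fit <- adjusted_mortality_model(ep, data.table(
    admission_id = character(), icd10_code = character(),
    category_hint = character()))
  yr <- fit[fit$term == "year" & fit$stratum == "whole"]
  expect_equal(nrow(yr), 1L)
  ## the generator's secular decline shows up as OR < 1
  expect_lt(yr$or, 1)
  expect_true(all(c("whole", "shock", "nonshock") %in% fit$stratum))
})

test_that("deduplicated patients never exceed admissions, equality iff no repeats", {
  b <- small_bundle()
  dd <- deduplicate(b$episodes)
  sep <- b$episodes[b$episodes$is_sepsis == TRUE]
  expect_lte(nrow(dd), nrow(sep))
  uni <- sep[!duplicated(sep$patient_id)]
  expect_equal(nrow(deduplicate(uni)), nrow(uni))
})
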