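test_that("write/read round-trip reproduces every field and is idempotent", {
  cfg <- sim_config(n_admissions_per_year = 60, years = 2014:2016, seed = 7)
  sim <- simulate_claims(cfg)
  d1 <- file.path(tempdir(), "rt1"); d2 <- file.path(tempdir(), "rt2")
  write_claims(sim, d1)
  back <- read_claims(file.path(d1, "admissions.csv"),
                      file.path(d1, "diagnoses.csv"),
                      file.path(d1, "events.csv"))
  expect_equal(nrow(back$admissions), nrow(sim$admissions))
  expect_setequal(back$admissions$admission_id, sim$admissions$admission_id)
  orig <- data.table::as.data.table(sim$admissions)[order(admission_id)]
  expect_equal(as.data.frame(back$admissions[order(admission_id)]),
               as.data.frame(orig))
  expect_equal(nrow(back$events), nrow(sim$events))
  ## second write is byte-identical
  write_claims(back, d2)
  for (f in c("admissions.csv", "diagnoses.csv", "events.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("referential and invariant violations are rejected with row numbers", {
  fx <- make_fixture("all_negative")
  bad_ev <- rbind(fx$events,
                  data.table(admission_id = "C01", event_type = "oxygen_therapy",
                             agent_id = "", day = 99L))
  expect_error(validate_claims(fx$admissions, fx$diagnoses, bad_ev),
               "day outside \\[1, los_days\\]")
  orphan <- rbind(fx$events,
                  data.table(admission_id = "ZZZ", event_type = "blood_culture",
                             agent_id = "", day = 1L))
  expect_error(validate_claims(fx$admissions, fx$diagnoses, orphan),
               "not found in admissions")
  noagent <- rbind(fx$events,
                   data.table(admission_id = "C01",
                              event_type = "iv_antibiotic",
                              agent_id = "", day = 1L))
  expect_error(validate_claims(fx$admissions, fx$diagnoses, noagent),
               "agent_id")
  baddx <- data.table(admission_id = "C01", icd10_code = "123",
                      category_hint = "")
  expect_error(validate_claims(fx$admissions, baddx, fx$events),
               "icd10_code")
})

test_that("empty events file reads as an empty event set without error", {
  fx <- make_fixture("all_negative")
  d <- file.path(tempdir(), "empty_ev")
  fx$events <- fx$events[0]
  write_claims(fx, d)
  back <- read_claims(file.path(d, "admissions.csv"),
                      file.path(d, "diagnoses.csv"),
                      file.path(d, "events.csv"))
  expect_equal(nrow(back$events), 0L)
})

test_that("cohort filter applies the 18-year boundary and missing-data rules", {
  adm <- rbind(
    adm_base <- data.table(admission_id = c("X1", "X2", "X3", "X4", "X5"),
                           patient_id = paste0("P", 1:5),
                           admission_year = 2015L,
                           age = c(17L, 18L, 90L, NA, 40L),
                           sex = c("male", "female", "male", "male", NA),
                           bmi = 22, los_days = 5L,
                           died_in_hospital = FALSE,
                           death_day = NA_integer_, icu_days = "",
                           maintenance_dialysis = FALSE))
  out <- filter_cohort(adm, quiet = TRUE)
  expect_setequal(out$admission_id, c("X2", "X3"))
  expect_equal(attr(out, "removed"),
               c(missing_demographics = 2L, under_18 = 1L))
  ## idempotent and order-preserving
  out2 <- filter_cohort(out, quiet = TRUE)
  expect_equal(out2$admission_id, out$admission_id)
  expect_equal(attr(out2, "removed"),
               c(missing_demographics = 0L, under_18 = 0L))
  ## all-valid input passes through unchanged
  ok <- adm[2:3]
  expect_equal(filter_cohort(ok, quiet = TRUE)$admission_id,
               ok$admission_id)
})

test_that("ICU day-set encoding round-trips", {
  sets <- list(integer(0), 3L, c(2L, 3L, 4L), c(10L, 12L))
  enc <- format_day_set(sets)
  expect_equal(enc, c("", "3", "2;3;4", "10;12"))
  expect_equal(parse_day_set(enc), sets)
})

test_that("code lists round-trip through YAML and validate categories", {
  cl <- default_code_lists()
  p <- tempfile(fileext = ".yaml")
  write_code_lists(cl, p)
  back <- read_code_lists(p)
  expect_equal(back$dysfunction, cl$dysfunction)
  expect_equal(back$antibiotics, cl$antibiotics)
  broken <- cl
  broken$dysfunction$hepatic <- NULL
  expect_error(write_code_lists(broken, p), "hepatic")
  ## prefix vs exact matching
  expect_true(icd10_match("K720", c("K72"), "prefix"))
  expect_false(icd10_match("K720", c("K72"), "exact"))
  expect_true(icd10_match("K72", c("K72"), "exact"))
})
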