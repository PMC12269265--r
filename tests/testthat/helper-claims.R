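library(data.table)

## Random "event soup" admissions for phenotyper stress tests: arbitrary
## cultures, antibiotic courses with gaps and switches, support events, and
## occasional in-hospital death. Valid claims, but with no intent to satisfy
## or violate the case definition — the oracle decides.
random_admission <- function(i) {
  los <- sample(1:20, 1)
  died <- runif(1) < 0.3
  death_day <- if (died) sample(max(1, los - 2):los, 1) else NA_integer_
  adm <- data.table(
    admission_id = sprintf("R%05d", i), patient_id = sprintf("RP%05d", i),
    admission_year = sample(2010:2020, 1), age = sample(18:95, 1),
    sex = sample(c("male", "female"), 1), bmi = 22,
    los_days = los, died_in_hospital = died, death_day = death_day,
    icu_days = "", maintenance_dialysis = runif(1) < 0.2)
  ev <- list()
  for (k in seq_len(rpois(1, 1.2)))
    ev[[length(ev) + 1]] <- data.table(
      admission_id = adm$admission_id, event_type = "blood_culture",
      agent_id = "", day = sample(1:los, 1))
  for (k in seq_len(rpois(1, 5)))
    ev[[length(ev) + 1]] <- data.table(
      admission_id = adm$admission_id, event_type = "iv_antibiotic",
      agent_id = sample(c("ABX01", "ABX02", "ABX03"), 1),
      day = sample(1:los, 1))
  for (type in c("vasopressor", "oxygen_therapy", "mechanical_ventilation",
                 "renal_replacement", "hydrocortisone"))
    if (runif(1) < 0.25)
      ev[[length(ev) + 1]] <- data.table(
        admission_id = adm$admission_id, event_type = type,
        agent_id = if (type == "vasopressor") "NORAD" else "",
        day = sample(1:los, 1))
  events <- if (length(ev)) rbindlist(ev) else
    data.table(admission_id = character(), event_type = character(),
               agent_id = character(), day = integer())
  dx <- if (runif(1) < 0.2)
    data.table(admission_id = adm$admission_id,
               icd10_code = sample(c("K720", "D695", "E872", "I10"), 1),
               category_hint = "")
  else data.table(admission_id = character(), icd10_code = character(),
                  category_hint = character())
  list(admission = adm, diagnoses = dx, events = events)
}

## Episode table assembled directly from generator ground truth (bypasses
## the phenotyper); used to unit-test the reporting layer at sizes where
## event-level phenotyping would dominate the runtime.
episodes_from_truth <- function(sim) {
  adm <- as.data.table(sim$admissions)
  tr <- as.data.table(sim$truth)
  d <- merge(adm, tr, by = "admission_id")
  icu_sets <- parse_day_set(d$icu_days)
  data.table(
    admission_id = d$admission_id, patient_id = d$patient_id,
    admission_year = d$admission_year, age = d$age, sex = d$sex,
    bmi = d$bmi, los_days = d$los_days,
    died_in_hospital = d$died_in_hospital,
    icu_admission = lengths(icu_sets) > 0L, icu_los = lengths(icu_sets),
    is_sepsis = d$is_sepsis, is_shock = d$is_shock,
    is_community_onset = d$is_community_onset,
    culture_day = ifelse(d$is_sepsis, 1L, NA_integer_),
    antibiotic_start_day = ifelse(d$is_sepsis, 1L, NA_integer_),
    qualifying_days = ifelse(d$is_sepsis, 4L, NA_integer_),
    qualified_by_death = ifelse(d$is_sepsis, FALSE, NA),
    dysfunctions = d$dysfunctions,
    vasopressor_days = as.integer(d$is_shock),
    hydrocortisone_days = 0L,
    antibiotic_days = ifelse(d$is_sepsis, 7L, 0L))
}
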