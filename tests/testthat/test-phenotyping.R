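one_adm <- function(los, died = FALSE, death_day = NA_integer_,
                    dialysis = FALSE) {
  data.table(admission_id = "T1", patient_id = "PT1",
             admission_year = 2015L, age = 60L, sex = "male", bmi = 22,
             los_days = as.integer(los), died_in_hospital = died,
             death_day = as.integer(death_day), icu_days = "",
             maintenance_dialysis = dialysis)
}
evs <- function(...) rbindlist(list(...))
ev1 <- function(type, days, agent = "")
  data.table(admission_id = "T1", event_type = type, agent_id = agent,
             day = as.integer(days))
no_dx <- data.table(admission_id = character(), icd10_code = character(),
                    category_hint = character())

test_that("infection window: qualifying course, absence cases, death exception", {
  ## culture day 3, antibiotics days 3-6, alive -> (3, 3, 4 days, no death)
  w <- detect_infection(one_adm(10),
                        evs(ev1("blood_culture", 3),
                            ev1("iv_antibiotic", 3:6, "ABX01")))
  expect_equal(w[c("culture_day", "antibiotic_start_day", "qualifying_days")],
               list(culture_day = 3L, antibiotic_start_day = 3L,
                    qualifying_days = 4L))
  expect_false(w$qualified_by_death)
  ## no blood culture -> absent
  expect_null(detect_infection(one_adm(10),
                               ev1("iv_antibiotic", 1:6, "ABX01")))
  ## culture day 1, antibiotics days 2-3, death day 3 -> death exception
  w <- detect_infection(one_adm(3, died = TRUE, death_day = 3),
                        evs(ev1("blood_culture", 1),
                            ev1("iv_antibiotic", 2:3, "ABX01")))
  expect_equal(w, list(culture_day = 1L, antibiotic_start_day = 2L,
                       qualifying_days = 2L, qualified_by_death = TRUE))
  ## culture day 10, antibiotics 13-20 -> start outside the ±2-day window
  expect_null(detect_infection(one_adm(25),
                               evs(ev1("blood_culture", 10),
                                   ev1("iv_antibiotic", 13:20, "ABX01"))))
})

test_that("strict single-agent policy breaks runs that agent switches sustain", {
  ## culture day 2: ABX01 starts day 4 (window edge) but stops after 2 days;
  ## ABX02 sustains the run from day 6, which is outside the ±2-day window,
  ## so strict mode finds no qualifying course while permissive mode does
  ev <- evs(ev1("blood_culture", 2),
            ev1("iv_antibiotic", 4:5, "ABX01"),
            ev1("iv_antibiotic", 6:9, "ABX02"))
  perm <- detect_infection(one_adm(12), ev)
  expect_equal(perm$antibiotic_start_day, 4L)
  expect_equal(perm$qualifying_days, 6L)
  expect_null(detect_infection(one_adm(12), ev, policy = "strict"))
  ## a same-agent switch inside the window qualifies in both modes
  ev2 <- evs(ev1("blood_culture", 4),
             ev1("iv_antibiotic", 4:5, "ABX01"),
             ev1("iv_antibiotic", 6:9, "ABX02"))
  expect_equal(detect_infection(one_adm(12), ev2)$antibiotic_start_day, 4L)
  expect_equal(detect_infection(one_adm(12), ev2,
                                policy = "strict")$antibiotic_start_day, 6L)
})

test_that("an agent restarted within the lookback is not newly initiated", {
  ## ABX01 given day 1, again days 3-6: the day-3 dose is not a new start
  ## (dose within the 2-day lookback), and no 4-day run exists from day 1
  ev <- evs(ev1("blood_culture", 3),
            ev1("iv_antibiotic", c(1, 3, 4, 5, 6), "ABX01"))
  expect_null(detect_infection(one_adm(10), ev))
  ## with a 1-day lookback the day-3 dose counts as new and the run holds
  expect_equal(detect_infection(one_adm(10), ev, lookback = 1L)$
                 antibiotic_start_day, 3L)
})

test_that("dysfunction categories: treatments, code matches, dialysis exclusion", {
  ## RRT with and without maintenance dialysis
  expect_equal(detect_dysfunctions(one_adm(10), no_dx,
                                   ev1("renal_replacement", 3)), "renal")
  expect_equal(detect_dysfunctions(one_adm(10, dialysis = TRUE), no_dx,
                                   ev1("renal_replacement", 3)),
               character(0))
  ## hepatic code + oxygen event
  dx <- data.table(admission_id = "T1", icd10_code = "K721",
                   category_hint = "")
  got <- detect_dysfunctions(one_adm(10), dx, ev1("oxygen_therapy", 2))
  expect_setequal(got, c("respiratory", "hepatic"))
})

test_that("classification combines infection, dysfunction, shock and onset rules", {
  base <- evs(ev1("blood_culture", 2), ev1("iv_antibiotic", 2:6, "ABX01"))
  ## vasopressor implies circulatory dysfunction and shock
  ep <- classify(one_adm(12), no_dx, rbind(base, ev1("vasopressor", 2, "NORAD")))
  expect_true(ep$is_sepsis); expect_true(ep$is_shock)
  expect_equal(ep$dysfunctions, "circulatory")
  ## infection without dysfunction is not sepsis
  ep <- classify(one_adm(12), no_dx, base)
  expect_false(ep$is_sepsis)
  ## culture day 2 but antibiotic start day 3: not community onset
  ep <- classify(one_adm(12), no_dx,
                 evs(ev1("blood_culture", 2),
                     ev1("iv_antibiotic", 3:7, "ABX01"),
                     ev1("oxygen_therapy", 3)))
  expect_true(ep$is_sepsis)
  expect_false(ep$is_community_onset)
})

test_that("monotonicity: adding a vasopressor never unmakes sepsis; no events means all-false", {
  ev <- evs(ev1("blood_culture", 2), ev1("iv_antibiotic", 2:6, "ABX01"),
            ev1("oxygen_therapy", 3))
  before <- classify(one_adm(12), no_dx, ev)
  after <- classify(one_adm(12), no_dx,
                    rbind(ev, ev1("vasopressor", 3, "NORAD")))
  expect_true(before$is_sepsis)
  expect_true(after$is_sepsis)
  expect_true(after$is_shock)
  empty <- classify(one_adm(12), no_dx, ev1("blood_culture", integer(0)))
  expect_false(empty$is_sepsis)
  expect_false(empty$is_shock)
  expect_false(empty$is_community_onset)
})

test_that("vectorised driver equals per-admission classification on the fixtures", {
  for (nm in c("worked_example_16", "death_exception", "all_negative")) {
    fx <- make_fixture(nm)
    ep <- classify_admissions(fx)
    for (i in seq_len(nrow(fx$admissions))) {
      a <- fx$admissions[i]
      single <- classify(a, fx$diagnoses[admission_id == a$admission_id],
                         fx$events[admission_id == a$admission_id])
      row <- ep[admission_id == a$admission_id]
      expect_equal(row$is_sepsis, single$is_sepsis, info = a$admission_id)
      expect_equal(row$is_shock, single$is_shock, info = a$admission_id)
      expect_equal(row$dysfunctions, single$dysfunctions,
                   info = a$admission_id)
      expect_equal(row$culture_day, single$culture_day,
                   info = a$admission_id)
    }
    ## and both match the hand-evaluated expectations
    cmp <- merge(ep, fx$expected, by = "admission_id",
                 suffixes = c("", ".exp"))
    expect_equal(cmp$is_sepsis, cmp$is_sepsis.exp)
    expect_equal(cmp$is_shock, cmp$is_shock.exp)
    expect_equal(cmp$is_community_onset, cmp$is_community_onset.exp)
  }
})

test_that("deduplication keeps the earliest sepsis admission per patient", {
  ep <- data.table(
    admission_id = c("A2", "A1", "B1", "C1", "C2"),
    patient_id = c("P1", "P1", "P2", "P3", "P3"),
    admission_year = c(2015L, 2012L, 2013L, 2014L, 2014L),
    is_sepsis = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    died_in_hospital = FALSE, is_shock = FALSE)
  dd <- deduplicate(ep)
  ## earliest year wins; same-year ties break on admission_id
  expect_setequal(dd$admission_id, c("A1", "B1", "C1"))
  expect_equal(attr(dd, "n_removed"), 2L)
  ## all-unique input is identity
  uni <- ep[c(2, 3)]
  expect_equal(nrow(deduplicate(uni)), 2L)
})

test_that("every sepsis episode is exactly one of shock or non-shock", {
  sim <- simulate_claims(sim_config(n_admissions_per_year = 500,
                                    years = 2010:2012, seed = 5))
  ep <- classify_admissions(sim)
  sep <- ep[is_sepsis == TRUE]
  expect_equal(sum(sep$is_shock) + sum(!sep$is_shock), nrow(sep))
  ## community onset requires an early culture
  expect_true(all(!ep$is_community_onset[!is.na(ep$culture_day) &
                                           ep$culture_day > 2]))
})
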