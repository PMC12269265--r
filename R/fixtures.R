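#' Hand-built phenotyping fixtures
#'
#' Returns tiny claims tables (≤ 20 admissions) whose expected phenotyping
#' verdicts were evaluated by hand against the case definitions; the
#' expected verdicts ship with the fixture in `$expected`.
#'
#' Catalog:
#' \describe{
#'   \item{`"worked_example_16"`}{16 admissions spanning every rule branch:
#'     qualifying windows at both ends of the ±2-day culture window, the
#'     death exception (positive with dysfunction, negative without),
#'     out-of-window starts, 3-day survivor courses, gap-broken runs,
#'     agent-switch coverage, maintenance-dialysis RRT suppression,
#'     vasopressor-defined shock and the 48-hour community-onset boundary.}
#'   \item{`"death_exception"`}{one admission: blood culture day 1,
#'     antibiotics days 2–4, death on day 4, oxygen therapy — sepsis.}
#'   \item{`"all_negative"`}{three admissions, none qualifying.}
#' }
#'
#' @param name Fixture name.
#' @return A `claims` object with an extra `expected` data.table
#'   (`admission_id`, `is_sepsis`, `is_shock`, `is_community_onset`).
#' @export
make_fixture <- function(name) {
  fixtures <- c("worked_example_16", "death_exception", "all_negative")
  if (!name %in% fixtures)
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "))
  switch(name,
         worked_example_16 = fixture_worked_example(),
         death_exception = fixture_death_exception(),
         all_negative = fixture_all_negative())
}

adm_row <- function(id, los, died = FALSE, death_day = NA_integer_,
                    year = 2015L, age = 70L, sex = "male", bmi = 22,
                    icu = "", dialysis = FALSE, patient = NULL) {
  data.table(admission_id = id, patient_id = patient %||% paste0("P", id),
             admission_year = year, age = age, sex = sex, bmi = bmi,
             los_days = as.integer(los), died_in_hospital = died,
             death_day = as.integer(death_day), icu_days = icu,
             maintenance_dialysis = dialysis)
}

ev_rows <- function(id, type, days, agent = "") {
  data.table(admission_id = id, event_type = type, agent_id = agent,
             day = as.integer(days))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_worked_example <- function() {
  A <- list(); E <- list(); D <- list()
  exp_row <- function(id, sepsis = FALSE, shock = FALSE, co = FALSE)
    data.table(admission_id = id, is_sepsis = sepsis, is_shock = shock,
               is_community_onset = co)
  X <- list()

  ## A01 classic hospital-onset sepsis: culture d3, abx d3-6, oxygen
  A$a01 <- adm_row("A01", 12)
  E$a01 <- rbind(ev_rows("A01", "blood_culture", 3),
                 ev_rows("A01", "iv_antibiotic", 3:6, "ABX01"),
                 ev_rows("A01", "oxygen_therapy", 3:4))
  X$a01 <- exp_row("A01", sepsis = TRUE)

  ## A02 community-onset septic shock: culture d1, abx d1-5, vasopressor d2
  A$a02 <- adm_row("A02", 20, icu = "2;3;4")
  E$a02 <- rbind(ev_rows("A02", "blood_culture", 1),
                 ev_rows("A02", "iv_antibiotic", 1:5, "ABX02"),
                 ev_rows("A02", "vasopressor", 2, "NORAD"))
  X$a02 <- exp_row("A02", sepsis = TRUE, shock = TRUE, co = TRUE)

  ## A03 death exception: culture d1, abx d2-3, death d3, oxygen d2
  A$a03 <- adm_row("A03", 3, died = TRUE, death_day = 3)
  E$a03 <- rbind(ev_rows("A03", "blood_culture", 1),
                 ev_rows("A03", "iv_antibiotic", 2:3, "ABX01"),
                 ev_rows("A03", "oxygen_therapy", 2))
  X$a03 <- exp_row("A03", sepsis = TRUE, co = TRUE)

  ## A04 antibiotics + dysfunction but no blood culture
  A$a04 <- adm_row("A04", 10)
  E$a04 <- rbind(ev_rows("A04", "iv_antibiotic", 1:6, "ABX03"),
                 ev_rows("A04", "oxygen_therapy", 1:2))
  X$a04 <- exp_row("A04")

  ## A05 culture without any antibiotics
  A$a05 <- adm_row("A05", 8)
  E$a05 <- rbind(ev_rows("A05", "blood_culture", 2),
                 ev_rows("A05", "oxygen_therapy", 2:3))
  X$a05 <- exp_row("A05")

  ## A06 start outside the ±2-day window: culture d10, abx d13-20
  A$a06 <- adm_row("A06", 25)
  E$a06 <- rbind(ev_rows("A06", "blood_culture", 10),
                 ev_rows("A06", "iv_antibiotic", 13:20, "ABX01"),
                 ev_rows("A06", "oxygen_therapy", 10:12))
  X$a06 <- exp_row("A06")

  ## A07 3-day course, survivor
  A$a07 <- adm_row("A07", 10)
  E$a07 <- rbind(ev_rows("A07", "blood_culture", 2),
                 ev_rows("A07", "iv_antibiotic", 2:4, "ABX04"),
                 ev_rows("A07", "oxygen_therapy", 2))
  X$a07 <- exp_row("A07")

  ## A08 presumed infection but no organ dysfunction
  A$a08 <- adm_row("A08", 14)
  E$a08 <- rbind(ev_rows("A08", "blood_culture", 3),
                 ev_rows("A08", "iv_antibiotic", 3:7, "ABX01"))
  X$a08 <- exp_row("A08")

  ## A09 RRT under maintenance dialysis: renal category suppressed
  A$a09 <- adm_row("A09", 14, dialysis = TRUE)
  E$a09 <- rbind(ev_rows("A09", "blood_culture", 2),
                 ev_rows("A09", "iv_antibiotic", 2:6, "ABX01"),
                 ev_rows("A09", "renal_replacement", 3:5))
  X$a09 <- exp_row("A09")

  ## A10 identical to A09 but acute RRT (no maintenance dialysis)
  A$a10 <- adm_row("A10", 14)
  E$a10 <- rbind(ev_rows("A10", "blood_culture", 2),
                 ev_rows("A10", "iv_antibiotic", 2:6, "ABX01"),
                 ev_rows("A10", "renal_replacement", 3:5))
  X$a10 <- exp_row("A10", sepsis = TRUE, co = TRUE)

  ## A11 community-onset boundary fails: culture d2 but abx start d3
  A$a11 <- adm_row("A11", 12)
  E$a11 <- rbind(ev_rows("A11", "blood_culture", 2),
                 ev_rows("A11", "iv_antibiotic", 3:7, "ABX05"),
                 ev_rows("A11", "oxygen_therapy", 3))
  X$a11 <- exp_row("A11", sepsis = TRUE)

  ## A12 start at the lower window edge: culture d5, abx d3-8, ventilation
  A$a12 <- adm_row("A12", 15)
  E$a12 <- rbind(ev_rows("A12", "blood_culture", 5),
                 ev_rows("A12", "iv_antibiotic", 3:8, "ABX01"),
                 ev_rows("A12", "mechanical_ventilation", 4:6))
  X$a12 <- exp_row("A12", sepsis = TRUE)

  ## A13 agent switch keeps the run alive; hepatic ICD code dysfunction
  A$a13 <- adm_row("A13", 12)
  E$a13 <- rbind(ev_rows("A13", "blood_culture", 4),
                 ev_rows("A13", "iv_antibiotic", 4:5, "ABX01"),
                 ev_rows("A13", "iv_antibiotic", 6:9, "ABX02"))
  D$a13 <- data.table(admission_id = "A13", icd10_code = "K720",
                      category_hint = "organ_dysfunction")
  X$a13 <- exp_row("A13", sepsis = TRUE)

  ## A14 zero-antibiotic day breaks the run (d4,5 then gap, then d7,8)
  A$a14 <- adm_row("A14", 12)
  E$a14 <- rbind(ev_rows("A14", "blood_culture", 4),
                 ev_rows("A14", "iv_antibiotic", c(4, 5, 7, 8), "ABX01"),
                 ev_rows("A14", "oxygen_therapy", 4))
  X$a14 <- exp_row("A14")

  ## A15 shock with circulatory as the only dysfunction
  A$a15 <- adm_row("A15", 18)
  E$a15 <- rbind(ev_rows("A15", "blood_culture", 6),
                 ev_rows("A15", "iv_antibiotic", 5:9, "ABX01"),
                 ev_rows("A15", "vasopressor", 6:7, "NORAD"))
  X$a15 <- exp_row("A15", sepsis = TRUE, shock = TRUE)

  ## A16 death exception satisfied but no dysfunction: still negative
  A$a16 <- adm_row("A16", 6, died = TRUE, death_day = 6)
  E$a16 <- rbind(ev_rows("A16", "blood_culture", 3),
                 ev_rows("A16", "iv_antibiotic", 5:6, "ABX01"))
  X$a16 <- exp_row("A16")

  finish_fixture(A, D, E, X)
}

fixture_death_exception <- function() {
  A <- list(a1 = adm_row("B01", 4, died = TRUE, death_day = 4))
  E <- list(a1 = rbind(ev_rows("B01", "blood_culture", 1),
                       ev_rows("B01", "iv_antibiotic", 2:4, "ABX01"),
                       ev_rows("B01", "oxygen_therapy", 2)))
  X <- list(a1 = data.table(admission_id = "B01", is_sepsis = TRUE,
                            is_shock = FALSE, is_community_onset = TRUE))
  finish_fixture(A, list(), E, X)
}

fixture_all_negative <- function() {
  A <- list(a1 = adm_row("C01", 5),
            a2 = adm_row("C02", 9),
            a3 = adm_row("C03", 7))
  E <- list(a1 = ev_rows("C01", "oxygen_therapy", 1:2),
            a2 = rbind(ev_rows("C02", "blood_culture", 1),
                       ev_rows("C02", "iv_antibiotic", 4:8, "ABX01")),
            a3 = ev_rows("C03", "iv_antibiotic", 1:7, "ABX02"))
  X <- lapply(c("C01", "C02", "C03"), function(id)
    data.table(admission_id = id, is_sepsis = FALSE, is_shock = FALSE,
               is_community_onset = FALSE))
  finish_fixture(A, list(), E, X)
}

finish_fixture <- function(A, D, E, X) {
  adm <- data.table::rbindlist(A)
  dx <- if (length(D)) data.table::rbindlist(D) else
    data.table(admission_id = character(), icd10_code = character(),
               category_hint = character())
  ev <- data.table::rbindlist(E)
  out <- new_claims(adm, dx, ev)
  out$expected <- data.table::rbindlist(X)
  validate_claims(adm, dx, ev)
  out
}
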