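#' @importFrom data.table := .N .SD data.table as.data.table fread fwrite setcolorder setorder copy
NULL

# Fixed column orders for the three claims tables. Calendar convention:
# integer hospital days with admission day = 1; absolute dates are never
# needed beyond admission_year.
ADMISSION_COLS <- c("admission_id", "patient_id", "admission_year", "age",
                    "sex", "bmi", "los_days", "died_in_hospital", "death_day",
                    "icu_days", "maintenance_dialysis")
DIAGNOSIS_COLS <- c("admission_id", "icd10_code", "category_hint")
EVENT_COLS     <- c("admission_id", "event_type", "agent_id", "day")

EVENT_TYPES <- c("blood_culture", "iv_antibiotic", "vasopressor",
                 "mechanical_ventilation", "oxygen_therapy",
                 "renal_replacement", "hydrocortisone")

#' Parse and format hospital-day sets
#'
#' ICU stays are stored in the admissions table as a semicolon-separated list
#' of integer hospital days (e.g. `"3;4;5"`); an empty string means no ICU
#' stay.
#'
#' @param x Character vector of encoded day sets.
#' @return `parse_day_set()` returns a list of integer vectors;
#'   `format_day_set()` the inverse.
#' @export
parse_day_set <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) as.integer(v[nzchar(v)]))
}

#' @rdname parse_day_set
#' @param days A list of integer vectors.
#' @export
format_day_set <- function(days) {
  vapply(days, function(v) paste(sort(unique(as.integer(v))), collapse = ";"),
         character(1))
}

new_claims <- function(admissions, diagnoses, events) {
  structure(list(admissions = admissions, diagnoses = diagnoses,
                 events = events), class = "claims")
}

#' @export
print.claims <- function(x, ...) {
  cat("<claims> ", nrow(x$admissions), " admissions, ",
      nrow(x$diagnoses), " diagnoses, ", nrow(x$events), " events\n", sep = "")
  yrs <- range(x$admissions$admission_year)
  cat("  years ", yrs[1], "-", yrs[2], "\n", sep = "")
  invisible(x)
}

check_columns <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing))
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

#' Validate a claims triplet
#'
#' Enforces the row invariants (positive LOS, death day within stay and
#' consistent with the mortality flag, ICU days within the stay, ICD-10
#' syntax, event days within the parent stay, antibiotic events carrying an
#' agent id) and referential integrity (every diagnosis/event admission_id
#' must resolve to an admission). Violations are reported with row numbers.
#'
#' @param admissions,diagnoses,events The three claims tables.
#' @return Invisibly, a validated `claims` object.
#' @export
validate_claims <- function(admissions, diagnoses, events) {
  admissions <- as.data.table(admissions)
  diagnoses  <- as.data.table(diagnoses)
  events     <- as.data.table(events)
  check_columns(admissions, ADMISSION_COLS, "admissions")
  check_columns(diagnoses, DIAGNOSIS_COLS, "diagnoses")
  check_columns(events, EVENT_COLS, "events")

  bad_row <- function(cond, what, msg) {
    idx <- which(cond)
    if (length(idx))
      stop("integrity error in ", what, " row(s) ",
           paste(utils::head(idx, 5), collapse = ", "),
           if (length(idx) > 5) " ..." else "", ": ", msg, call. = FALSE)
  }

  if (anyDuplicated(admissions$admission_id))
    stop("integrity error: duplicate admission_id in admissions", call. = FALSE)
  if (!is.numeric(admissions$los_days) || anyNA(admissions$los_days))
    stop("parse error: los_days must be numeric and non-missing", call. = FALSE)
  bad_row(admissions$los_days < 1, "admissions", "los_days < 1")
  bad_row(!is.na(admissions$death_day) & !admissions$died_in_hospital,
          "admissions", "death_day present without died_in_hospital")
  bad_row(!is.na(admissions$death_day) &
            admissions$death_day > admissions$los_days,
          "admissions", "death_day > los_days")
  bad_row(admissions$died_in_hospital & is.na(admissions$death_day),
          "admissions", "died_in_hospital without death_day")
  icu <- parse_day_set(admissions$icu_days)
  icu_ok <- mapply(function(d, los) !length(d) || (min(d) >= 1 && max(d) <= los),
                   icu, admissions$los_days)
  bad_row(!icu_ok, "admissions", "icu_days outside [1, los_days]")
  bad_row(!admissions$sex %in% c("male", "female") & !is.na(admissions$sex),
          "admissions", "sex must be 'male' or 'female'")

  if (nrow(diagnoses)) {
    bad_row(!grepl("^[A-Z][0-9]{2}", diagnoses$icd10_code), "diagnoses",
            "icd10_code must be an uppercase letter followed by >= 2 digits")
    orphan <- !diagnoses$admission_id %in% admissions$admission_id
    bad_row(orphan, "diagnoses", "admission_id not found in admissions")
  }
  if (nrow(events)) {
    if (!is.numeric(events$day) || anyNA(events$day))
      stop("parse error: event day must be numeric and non-missing", call. = FALSE)
    bad_row(!events$event_type %in% EVENT_TYPES, "events",
            "unknown event_type")
    orphan <- !events$admission_id %in% admissions$admission_id
    bad_row(orphan, "events", "admission_id not found in admissions")
    los <- admissions$los_days[match(events$admission_id,
                                     admissions$admission_id)]
    bad_row(events$day < 1 | events$day > los, "events",
            "day outside [1, los_days] of the parent admission")
    bad_row(events$event_type == "iv_antibiotic" &
              (is.na(events$agent_id) | !nzchar(events$agent_id)),
            "events", "iv_antibiotic events must carry an agent_id")
  }
  invisible(new_claims(admissions, diagnoses, events))
}

#' Read the three claims tables
#'
#' Reads `admissions`, `diagnoses` and `events` CSV files (UTF-8, fixed
#' documented headers, empty fields for missing values), validates all row
#' invariants and referential integrity, and returns a `claims` object.
#'
#' @param admissions_path,diagnoses_path,events_path CSV paths.
#' @return A `claims` list with elements `admissions`, `diagnoses`, `events`
#'   (each a `data.table`).
#' @export
read_claims <- function(admissions_path, diagnoses_path, events_path) {
  for (p in c(admissions_path, diagnoses_path, events_path))
    if (!file.exists(p)) stop("file not found: ", p)
  admissions <- fread(admissions_path, colClasses = list(
    character = c("admission_id", "patient_id", "sex", "icu_days")),
    na.strings = "")
  diagnoses <- fread(diagnoses_path, colClasses = "character",
                     na.strings = "")
  events <- fread(events_path, colClasses = list(
    character = c("admission_id", "event_type", "agent_id")),
    na.strings = "")
  if (nrow(diagnoses) == 0)
    diagnoses <- data.table(admission_id = character(),
                            icd10_code = character(),
                            category_hint = character())
  if (nrow(events) == 0)
    events <- data.table(admission_id = character(), event_type = character(),
                         agent_id = character(), day = integer())
  if ("agent_id" %in% names(events))
    events[, agent_id := ifelse(is.na(agent_id), "", agent_id)]
  admissions[, icu_days := ifelse(is.na(icu_days), "", icu_days)]
  if ("category_hint" %in% names(diagnoses))
    diagnoses[, category_hint := ifelse(is.na(category_hint), "",
                                        category_hint)]
  validate_claims(admissions, diagnoses, events)
}

#' Write claims tables
#'
#' Writes with a deterministic column order and row order so that identical
#' inputs produce byte-identical files; `read_claims()` of the output
#' reproduces every field. Missing values are written as empty fields.
#'
#' @param claims A `claims` object (or list with the three tables).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the three file paths.
#' @export
write_claims <- function(claims, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  validate_claims(claims$admissions, claims$diagnoses, claims$events)
  adm <- as.data.table(claims$admissions)[, ADMISSION_COLS, with = FALSE]
  dx  <- as.data.table(claims$diagnoses)[, DIAGNOSIS_COLS, with = FALSE]
  ev  <- as.data.table(claims$events)[, EVENT_COLS, with = FALSE]
  setorder(adm, admission_id)
  if (nrow(dx)) setorder(dx, admission_id, icd10_code)
  if (nrow(ev)) setorder(ev, admission_id, day, event_type, agent_id)
  paths <- file.path(dir, c("admissions.csv", "diagnoses.csv", "events.csv"))
  write_table(adm, paths[1])
  write_table(dx, paths[2])
  write_table(ev, paths[3])
  invisible(paths)
}

#' Write a single table deterministically
#'
#' @param rows A data.frame / data.table.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  fwrite(as.data.table(rows), path, na = "", quote = FALSE,
         logical01 = FALSE)
  invisible(path)
}

#' Apply the cohort inclusion criteria
#'
#' Keeps adult admissions (age >= 18) with non-missing age, sex and
#' in-hospital mortality status. This is filtering, not validation: rows
#' failing the criteria are dropped, and the counts removed per reason are
#' attached as the `"removed"` attribute (and reported via `message()`).
#' Idempotent and order-preserving.
#'
#' @param admissions Admissions table.
#' @param quiet Suppress the message.
#' @return The filtered admissions table with attribute `removed`, a named
#'   integer vector `c(missing_demographics =, under_18 =)`.
#' @export
filter_cohort <- function(admissions, quiet = FALSE) {
  adm <- as.data.table(admissions)
  miss <- is.na(adm$age) | is.na(adm$sex) | is.na(adm$died_in_hospital)
  young <- !miss & adm$age < 18
  out <- adm[!(miss | young)]
  removed <- c(missing_demographics = sum(miss), under_18 = sum(young))
  if (!quiet && sum(removed))
    message("filter_cohort: removed ", removed[["missing_demographics"]],
            " with missing demographics, ", removed[["under_18"]],
            " aged < 18")
  data.table::setattr(out, "removed", removed)
  out
}
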