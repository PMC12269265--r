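DYSFUNCTION_CATEGORIES <- c("circulatory", "respiratory", "renal", "hepatic",
                            "thrombocytopenia", "coagulopathy", "acidosis")

#' Detect a presumed serious infection window
#'
#' A presumed serious infection requires (a) a blood-culture event on some
#' day `c`; (b) a *new* IV antibiotic starting on a day `s` within ±2
#' calendar days of `c` (an agent is newly initiated on day `s` when it was
#' not administered on days `s-2`..`s-1` of the same admission; the lookback
#' is configurable); and (c) IV antibiotics administered on at least 4
#' consecutive calendar days starting at `s` — agent switches allowed under
#' the default `"permissive"` policy, single-agent runs required under
#' `"strict"` — or in-hospital death before the 4th day of therapy with
#' antibiotics continued through the day of death (the death exception).
#'
#' When several (culture, start) pairs qualify, the earliest is reported:
#' smallest culture day, then smallest start day.
#'
#' @param admission A one-row admissions table (list-like) for the patient.
#' @param events Events of that admission.
#' @param code_lists A [default_code_lists()] object; antibiotic events are
#'   restricted to listed agent ids.
#' @param lookback Days an agent must be absent before a dose counts as
#'   newly initiated (default 2).
#' @param policy `"permissive"` (any agent sustains the run) or `"strict"`
#'   (the run must be the starting agent's own).
#' @return A list `(culture_day, antibiotic_start_day, qualifying_days,
#'   qualified_by_death)`, or `NULL` when no pair qualifies.
#' @export
detect_infection <- function(admission, events, code_lists = default_code_lists(),
                             lookback = 2L, policy = c("permissive", "strict")) {
  policy <- match.arg(policy)
  ev <- as.data.table(events)
  cultures <- sort(unique(ev$day[ev$event_type == "blood_culture"]))
  abx <- ev[ev$event_type == "iv_antibiotic" &
              ev$agent_id %in% code_lists$antibiotics]
  if (!length(cultures) || !nrow(abx)) return(NULL)
  died <- isTRUE(admission$died_in_hospital)
  death_day <- if (died) admission$death_day else NA_integer_

  all_days <- sort(unique(abx$day))
  agent_days <- split(abx$day, abx$agent_id)
  ## new-start days per agent: no same-agent dose on the `lookback` days
  ## before
  starts <- lapply(agent_days, function(d) {
    d <- sort(unique(d))
    is_new <- vapply(d, function(x)
      !any(d >= x - lookback & d < x), logical(1))
    d[is_new]
  })

  run_from <- function(s, days) {
    r <- 0L
    while ((s + r) %in% days) r <- r + 1L
    r
  }

  best <- NULL
  for (cd in cultures) {
    cand <- data.table(
      agent = rep(names(starts), lengths(starts)),
      day = unlist(starts, use.names = FALSE))
    cand <- cand[cand$day >= cd - 2L & cand$day <= cd + 2L & cand$day >= 1L]
    if (!nrow(cand)) next
    setorder(cand, day)
    for (i in seq_len(nrow(cand))) {
      s <- cand$day[i]
      cover <- if (policy == "strict")
        sort(unique(agent_days[[cand$agent[i]]])) else all_days
      r <- run_from(s, cover)
      ok <- r >= 4L ||
        (died && !is.na(death_day) && death_day >= s &&
           death_day < s + 3L && r >= death_day - s + 1L)
      if (ok) {
        best <- list(culture_day = as.integer(cd),
                     antibiotic_start_day = as.integer(s),
                     qualifying_days = as.integer(r),
                     qualified_by_death = r < 4L)
        break
      }
    }
    if (!is.null(best)) break
  }
  best
}

#' Detect acute organ dysfunction categories
#'
#' Treatment-based categories: circulatory (≥1 vasopressor event),
#' respiratory (≥1 mechanical-ventilation or oxygen-therapy event), renal
#' (≥1 renal-replacement event, suppressed for patients on maintenance
#' dialysis so that only acute renal support counts). Code-based categories
#' (hepatic, thrombocytopenia, coagulopathy, acidosis): any diagnosis
#' matching the category's ICD-10 prefix set.
#'
#' @inheritParams detect_infection
#' @param diagnoses Diagnoses of the admission.
#' @return Character vector, a subset of the seven category names.
#' @export
detect_dysfunctions <- function(admission, diagnoses, events,
                                code_lists = default_code_lists()) {
  ev <- as.data.table(events)
  dx <- as.data.table(diagnoses)
  out <- character(0)
  if (any(ev$event_type == "vasopressor")) out <- c(out, "circulatory")
  if (any(ev$event_type %in% c("mechanical_ventilation", "oxygen_therapy")))
    out <- c(out, "respiratory")
  if (any(ev$event_type == "renal_replacement") &&
      !isTRUE(admission$maintenance_dialysis))
    out <- c(out, "renal")
  for (cat in c("hepatic", "thrombocytopenia", "coagulopathy", "acidosis")) {
    prefixes <- code_lists$dysfunction[[cat]]
    if (is.null(prefixes))
      stop("code_lists: dysfunction category '", cat, "' not defined")
    if (nrow(dx) && any(icd10_match(dx$icd10_code, prefixes,
                                    code_lists$matching)))
      out <- c(out, cat)
  }
  out
}

episode_row <- function(admission, infection, dysfunctions, ev) {
  has_vaso <- any(ev$event_type == "vasopressor")
  is_sepsis <- !is.null(infection) && length(dysfunctions) > 0
  is_shock <- is_sepsis && has_vaso
  is_co <- is_sepsis && infection$culture_day <= 2L &&
    infection$antibiotic_start_day <= 2L
  ndays <- function(type) length(unique(ev$day[ev$event_type == type]))
  data.table(
    admission_id = admission$admission_id,
    is_sepsis = is_sepsis, is_shock = is_shock, is_community_onset = is_co,
    culture_day = if (is.null(infection)) NA_integer_ else infection$culture_day,
    antibiotic_start_day = if (is.null(infection)) NA_integer_ else
      infection$antibiotic_start_day,
    qualifying_days = if (is.null(infection)) NA_integer_ else
      infection$qualifying_days,
    qualified_by_death = if (is.null(infection)) NA else
      infection$qualified_by_death,
    dysfunctions = paste(dysfunctions, collapse = ";"),
    vasopressor_days = ndays("vasopressor"),
    hydrocortisone_days = ndays("hydrocortisone"),
    antibiotic_days = ndays("iv_antibiotic"))
}

#' Classify one admission into a sepsis episode
#'
#' Combines [detect_infection()] and [detect_dysfunctions()]: sepsis is a
#' presumed serious infection together with at least one acute organ
#' dysfunction; septic shock is sepsis with at least one vasopressor
#' administration (so shock implies the circulatory category by
#' construction); community onset is sepsis with both blood culture and
#' antibiotic initiation on hospital day 1 or 2 (the 48-hour rule at
#' calendar-day resolution). Treatment-duration fields count distinct
#' calendar days with the respective event.
#'
#' @inheritParams detect_dysfunctions
#' @inheritParams detect_infection
#' @return A one-row data.table (a `SepsisEpisode`).
#' @export
classify <- function(admission, diagnoses, events,
                     code_lists = default_code_lists(), lookback = 2L,
                     policy = "permissive") {
  ev <- as.data.table(events)
  infection <- detect_infection(admission, ev, code_lists, lookback, policy)
  dys <- detect_dysfunctions(admission, diagnoses, ev, code_lists)
  episode_row(admission, infection, dys, ev)
}

#' Phenotype every admission in a claims set
#'
#' Vectorised driver over [classify()]'s logic: treatment-day counts and
#' dysfunction categories are computed by grouped aggregation, and the
#' infection-window search runs only on admissions that have both a blood
#' culture and an IV antibiotic event (no other admission can qualify).
#' Results are identical to calling [classify()] per admission.
#'
#' @param claims A `claims` object (admissions/diagnoses/events).
#' @param code_lists Code-list configuration.
#' @inheritParams detect_infection
#' @return A data.table with one `SepsisEpisode` row per admission, joined
#'   with `patient_id`, `admission_year`, demographics, ICU and outcome
#'   columns of the admissions table.
#' @export
classify_admissions <- function(claims, code_lists = default_code_lists(),
                                lookback = 2L, policy = "permissive") {
  adm <- as.data.table(claims$admissions)
  ev <- as.data.table(claims$events)
  dx <- as.data.table(claims$diagnoses)
  validate_code_lists(code_lists)

  id <- adm$admission_id
  n <- length(id)
  day_counts <- function(type) {
    sub <- ev[ev$event_type == type,
              list(nd = length(unique(day))), by = "admission_id"]
    out <- integer(n)
    out[match(sub$admission_id, id)] <- sub$nd
    out
  }
  vaso_days <- day_counts("vasopressor")
  hydro_days <- day_counts("hydrocortisone")
  abx_days <- day_counts("iv_antibiotic")
  has <- function(types) id %in% ev$admission_id[ev$event_type %in% types]
  has_resp <- has(c("mechanical_ventilation", "oxygen_therapy"))
  has_rrt <- has("renal_replacement")
  has_culture <- has("blood_culture")

  code_flag <- function(prefixes) {
    if (!nrow(dx)) return(logical(n))
    hit <- dx$admission_id[icd10_match(dx$icd10_code, prefixes,
                                       code_lists$matching)]
    id %in% hit
  }
  dys_mat <- cbind(
    circulatory = vaso_days > 0L,
    respiratory = has_resp,
    renal = has_rrt & !adm$maintenance_dialysis,
    hepatic = code_flag(code_lists$dysfunction$hepatic),
    thrombocytopenia = code_flag(code_lists$dysfunction$thrombocytopenia),
    coagulopathy = code_flag(code_lists$dysfunction$coagulopathy),
    acidosis = code_flag(code_lists$dysfunction$acidosis))
  any_dys <- rowSums(dys_mat) > 0L
  dys_chr <- character(n)
  w <- which(any_dys)
  if (length(w))
    dys_chr[w] <- apply(dys_mat[w, , drop = FALSE], 1, function(r)
      paste(DYSFUNCTION_CATEGORIES[r], collapse = ";"))

  ## infection-window search on candidate admissions only
  cand <- which(has_culture & abx_days > 0L)
  culture_day <- rep(NA_integer_, n)
  abx_start <- rep(NA_integer_, n)
  qual_days <- rep(NA_integer_, n)
  qual_death <- rep(NA, n)
  infected <- logical(n)
  if (length(cand)) {
    sub <- ev[ev$event_type %in% c("blood_culture", "iv_antibiotic") &
                ev$admission_id %in% id[cand]]
    ev_split <- split(sub, sub$admission_id)
    for (i in cand) {
      inf <- detect_infection(adm[i], ev_split[[id[i]]], code_lists,
                              lookback, policy)
      if (!is.null(inf)) {
        infected[i] <- TRUE
        culture_day[i] <- inf$culture_day
        abx_start[i] <- inf$antibiotic_start_day
        qual_days[i] <- inf$qualifying_days
        qual_death[i] <- inf$qualified_by_death
      }
    }
  }

  is_sepsis <- infected & any_dys
  is_shock <- is_sepsis & vaso_days > 0L
  is_co <- is_sepsis & culture_day <= 2L & abx_start <= 2L
  is_co[is.na(is_co)] <- FALSE

  icu_sets <- parse_day_set(adm$icu_days)
  data.table(
    admission_id = id, patient_id = adm$patient_id,
    admission_year = adm$admission_year, age = adm$age, sex = adm$sex,
    bmi = adm$bmi, los_days = adm$los_days,
    died_in_hospital = adm$died_in_hospital,
    icu_admission = lengths(icu_sets) > 0L,
    icu_los = lengths(icu_sets),
    is_sepsis = is_sepsis, is_shock = is_shock, is_community_onset = is_co,
    culture_day = culture_day, antibiotic_start_day = abx_start,
    qualifying_days = qual_days, qualified_by_death = qual_death,
    dysfunctions = dys_chr, vasopressor_days = vaso_days,
    hydrocortisone_days = hydro_days, antibiotic_days = abx_days)
}

#' Deduplicate sepsis episodes to the patient level
#'
#' Mortality-type analyses (in-hospital mortality, deaths per 1,000
#' inpatients) count each patient once: among a patient's sepsis
#' admissions, the earliest by `(admission_year, admission_id)` is kept.
#' Length-of-stay and proportion analyses keep every admission and should
#' not use this function.
#'
#' @param episodes Episode table from [classify_admissions()] (must carry
#'   `patient_id` and `admission_year`).
#' @return The sepsis-only, patient-level episode subset, with attribute
#'   `n_removed` (admissions dropped as repeats).
#' @export
deduplicate <- function(episodes) {
  ep <- as.data.table(episodes)[is_sepsis == TRUE]
  setorder(ep, patient_id, admission_year, admission_id)
  out <- ep[, .SD[1L], by = "patient_id"]
  setorder(out, admission_id)
  data.table::setattr(out, "n_removed", nrow(ep) - nrow(out))
  out[]
}
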