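#' Simulation configuration for the synthetic claims generator
#'
#' Assembles (and validates) the parameter set that [simulate_claims()]
#' consumes. The defaults target the headline magnitudes of nationwide
#' Japanese DPC sepsis surveillance: ~5.4% sepsis prevalence among
#' admissions, ~14.7% septic shock among sepsis, in-hospital mortality near
#' 36.5% (shock) / 20% (non-shock), ~50.7% ICU admission in shock vs ~19.2%
#' in non-shock sepsis, right-skewed length of stay (median 38 days in shock
#' vs mean 58), rising community-onset fraction, and a declining secular
#' mortality trend of ~0.96 odds per admission year in the shock stratum.
#' Synthetic runs therefore "look like" national claims data without
#' claiming to reproduce it.
#'
#' @param n_admissions_per_year Admissions generated per calendar year.
#' @param years Integer vector of admission years.
#' @param p_sepsis Baseline (mid-period) probability an admission is true
#'   sepsis.
#' @param sepsis_logit_drift Per-year additive drift of the sepsis logit
#'   (sepsis has grown over the surveillance decade).
#' @param p_shock_given_sepsis Probability a true sepsis admission is septic
#'   shock.
#' @param mortality_model Named list of logistic coefficients for in-hospital
#'   death among sepsis admissions: `intercept`, `per_year_log_OR` (year
#'   centred at `year_center`), `shock_log_OR`, `per_age_log_OR` (age centred
#'   at `age_center`), `male_log_OR`, `icu_log_OR`, and `comorbidity_log_OR`,
#'   a named vector over comorbidity categories.
#' @param p_death_nonsepsis Flat in-hospital mortality for non-sepsis
#'   admissions.
#' @param p_icu_given_shock,p_icu_given_nonshock,p_icu_background ICU
#'   admission probabilities for shock sepsis, non-shock sepsis and
#'   non-sepsis admissions.
#' @param los_model Log-normal location/scale per (stratum) with a shared
#'   per-year drift of the location (`per_year_meanlog_drift`): strata
#'   `shock_survivor`, `shock_died`, `nonshock_survivor`, `nonshock_died`,
#'   `background`.
#' @param p_community_onset Named list `shock`, `nonshock`: mid-period
#'   probability that a sepsis admission is community onset.
#' @param community_onset_logit_drift Per-year additive drift of the
#'   community-onset logit.
#' @param comorbidity_prev Named vector of marginal comorbidity prevalences
#'   (drawn independently; the joint distribution of comorbidities is not
#'   identified by published tables, so independence is assumed).
#' @param p_focus_coded Probability a sepsis admission carries an
#'   infection-focus diagnosis code.
#' @param infection_focus_dist Named probability vector over focus
#'   categories, conditional on a focus being coded.
#' @param p_hydrocortisone Named list `shock`, `nonshock`.
#' @param p_male Probability male.
#' @param age_mean,age_sd Normal age distribution, truncated to [18, 104].
#' @param bmi_mean,bmi_sd,p_bmi_missing BMI distribution and missingness.
#' @param readmission_rate Fraction of admissions that are second admissions
#'   of an already-generated patient (exercises deduplication).
#' @param near_miss_rates Named vector of per-admission probabilities, among
#'   non-sepsis admissions, of emitting deliberately almost-qualifying event
#'   patterns: `culture_no_abx`, `out_of_window`, `short_course`,
#'   `dialysis_rrt`. These stress the phenotyper and must classify negative.
#' @param p_background_abx,p_background_oxygen Rates of incidental antibiotic
#'   courses (without blood culture) and oxygen therapy among clean
#'   negatives.
#' @param year_center,age_center Centring constants of the mortality model.
#' @param seed Integer RNG seed; identical configs give byte-identical
#'   output.
#' @return A validated list with class `sim_config`.
#' @export
sim_config <- function(n_admissions_per_year = 10000,
                       years = 2010:2020,
                       p_sepsis = 0.054,
                       sepsis_logit_drift = 0.05,
                       p_shock_given_sepsis = 0.147,
                       mortality_model = list(
                         intercept = stats::qlogis(0.20),
                         per_year_log_OR = log(0.96),
                         shock_log_OR = 0.83,
                         per_age_log_OR = 0.025,
                         male_log_OR = log(1.15),
                         icu_log_OR = -0.10,
                         comorbidity_log_OR = c(malignancy = 0.26,
                                                chronic_renal = 0.18,
                                                heart_failure = 0.18)
                       ),
                       p_death_nonsepsis = 0.02,
                       p_icu_given_shock = 0.507,
                       p_icu_given_nonshock = 0.192,
                       p_icu_background = 0.03,
                       los_model = list(
                         shock_survivor    = c(meanlog = log(45), sdlog = 0.85),
                         shock_died        = c(meanlog = log(25), sdlog = 0.90),
                         nonshock_survivor = c(meanlog = log(26), sdlog = 0.85),
                         nonshock_died     = c(meanlog = log(18), sdlog = 0.90),
                         background        = c(meanlog = log(10), sdlog = 0.80),
                         per_year_meanlog_drift = -0.02
                       ),
                       p_community_onset = list(shock = 0.434, nonshock = 0.632),
                       community_onset_logit_drift = 0.06,
                       comorbidity_prev = c(hypertension = 0.296,
                                            diabetes = 0.197,
                                            malignancy = 0.195,
                                            ischemic_heart = 0.114,
                                            heart_failure = 0.087,
                                            chronic_respiratory = 0.073,
                                            cerebrovascular = 0.070,
                                            chronic_renal = 0.051),
                       p_focus_coded = 0.31,
                       infection_focus_dist = c(respiratory = 0.498,
                                                abdominal = 0.241,
                                                urogenital = 0.076,
                                                bone_soft_tissue = 0.054,
                                                blood = 0.001,
                                                other = 0.130),
                       p_hydrocortisone = list(shock = 0.132, nonshock = 0.056),
                       p_male = 0.55,
                       age_mean = 74, age_sd = 14,
                       bmi_mean = 21.6, bmi_sd = 4.2, p_bmi_missing = 0.05,
                       readmission_rate = 0.10,
                       near_miss_rates = c(culture_no_abx = 0.010,
                                           out_of_window = 0.010,
                                           short_course = 0.010,
                                           dialysis_rrt = 0.005),
                       p_background_abx = 0.05,
                       p_background_oxygen = 0.05,
                       year_center = 2015, age_center = 77,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(p_sepsis, p_shock_given_sepsis, p_death_nonsepsis,
             p_icu_given_shock, p_icu_given_nonshock, p_icu_background,
             unlist(p_community_onset), comorbidity_prev, p_focus_coded,
             unlist(p_hydrocortisone), p_male, p_bmi_missing,
             readmission_rate, near_miss_rates, p_background_abx,
             p_background_oxygen)
  if (any(probs < 0 | probs > 1))
    stop("sim_config: all probabilities must lie in [0, 1]")
  if (!length(years)) stop("sim_config: years must be non-empty")
  if (n_admissions_per_year < 1)
    stop("sim_config: n_admissions_per_year must be positive")
  sds <- vapply(cfg$los_model[setdiff(names(cfg$los_model),
                                      "per_year_meanlog_drift")],
                function(s) s[["sdlog"]], numeric(1))
  if (any(sds <= 0)) stop("sim_config: los_model sdlog must be > 0")
  if (sum(near_miss_rates) > 1)
    stop("sim_config: near_miss_rates must sum to <= 1")
  class(cfg) <- "sim_config"
  cfg
}

# Representative (placeholder) ICD-10 codes used by the generator; each
# matches exactly one category prefix of default_code_lists().
GEN_COMORBIDITY_CODE <- c(hypertension = "I10", diabetes = "E119",
                          malignancy = "C349", ischemic_heart = "I259",
                          heart_failure = "I500",
                          chronic_respiratory = "J449",
                          cerebrovascular = "I639", chronic_renal = "N189")
GEN_FOCUS_CODE <- c(respiratory = "J189", abdominal = "K650",
                    urogenital = "N390", bone_soft_tissue = "M860",
                    blood = "A419", other = "I330")
GEN_DYSFUNCTION_CODE <- c(hepatic = "K720", thrombocytopenia = "D695",
                          coagulopathy = "D65", acidosis = "E872")

#' Generate synthetic claims with ground-truth labels
#'
#' Draws a full synthetic inpatient claims extract: demographics, comorbidity
#' diagnoses, true sepsis/shock status and — conditional on true status —
#' event streams that satisfy the phenotyping rules for true cases (blood
#' culture, a new IV antibiotic course starting within ±2 days and running
#' ≥4 consecutive days or until death, ≥1 organ-dysfunction marker, and
#' vasopressors for shock) and deliberately *fail* them for negatives.
#' Near-miss negatives (culture without qualifying antibiotics, antibiotic
#' start outside the ±2-day window, 3-day courses with survival, RRT under
#' maintenance dialysis) are emitted at configurable rates to stress the
#' phenotyper. Identical seeds give byte-identical output.
#'
#' All draws happen in one seeded RNG stream in a fixed, documented order, so
#' the output is a pure function of the config.
#'
#' @param config A [sim_config()] object.
#' @param events If `FALSE`, skip diagnosis/event-stream construction and
#'   return only the admissions table and ground truth (cohort mode; used by
#'   the large statistical calibration studies, where refits use the
#'   ground-truth labels directly).
#' @return A list with class `claims` (plus `truth`): `admissions`,
#'   `diagnoses`, `events`, and `truth` (one row per admission:
#'   `admission_id`, `is_sepsis`, `is_shock`, `is_community_onset`,
#'   `dysfunctions` (semicolon-joined), `truth_class`).
#' @export
simulate_claims <- function(config = sim_config(), events = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_year <- length(cfg$years)
  n <- cfg$n_admissions_per_year * n_year

  year <- rep(cfg$years, each = cfg$n_admissions_per_year)
  yc <- year - cfg$year_center
  admission_id <- sprintf("A%07d", seq_len(n))

  ## -- demographics ---------------------------------------------------------
  age <- pmin(pmax(round(stats::rnorm(n, cfg$age_mean, cfg$age_sd)), 18L), 104L)
  sex <- ifelse(stats::runif(n) < cfg$p_male, "male", "female")
  bmi <- round(pmax(stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd), 10), 1)
  bmi[stats::runif(n) < cfg$p_bmi_missing] <- NA_real_

  comorb <- sapply(names(cfg$comorbidity_prev), function(cm)
    stats::runif(n) < cfg$comorbidity_prev[[cm]])

  ## -- true status ----------------------------------------------------------
  p_sep <- stats::plogis(stats::qlogis(cfg$p_sepsis) +
                           cfg$sepsis_logit_drift * yc)
  is_sepsis <- stats::runif(n) < p_sep
  is_shock <- is_sepsis & stats::runif(n) < cfg$p_shock_given_sepsis

  ## maintenance dialysis: tied to chronic renal disease, but never assigned
  ## to admissions whose acute renal dysfunction must count (fixed below)
  maintenance_dialysis <- stats::runif(n) <
    ifelse(comorb[, "chronic_renal"], 0.30, 0.005)

  ## -- ICU ------------------------------------------------------------------
  p_icu <- ifelse(is_shock, cfg$p_icu_given_shock,
                  ifelse(is_sepsis, cfg$p_icu_given_nonshock,
                         cfg$p_icu_background))
  icu <- stats::runif(n) < p_icu

  ## -- mortality ------------------------------------------------------------
  mm <- cfg$mortality_model
  lp <- mm$intercept + mm$per_year_log_OR * yc + mm$shock_log_OR * is_shock +
    mm$per_age_log_OR * (age - cfg$age_center) +
    mm$male_log_OR * (sex == "male") + mm$icu_log_OR * icu
  for (cm in names(mm$comorbidity_log_OR))
    lp <- lp + mm$comorbidity_log_OR[[cm]] * comorb[, cm]
  p_die <- ifelse(is_sepsis, stats::plogis(lp), cfg$p_death_nonsepsis)
  died <- stats::runif(n) < p_die

  ## -- length of stay -------------------------------------------------------
  lm_ <- cfg$los_model
  stratum <- ifelse(is_shock, ifelse(died, "shock_died", "shock_survivor"),
                    ifelse(is_sepsis,
                           ifelse(died, "nonshock_died", "nonshock_survivor"),
                           "background"))
  meanlog <- vapply(lm_[stratum], function(s) s[["meanlog"]], numeric(1)) +
    lm_$per_year_meanlog_drift * yc
  sdlog <- vapply(lm_[stratum], function(s) s[["sdlog"]], numeric(1))
  los <- pmax(1L, as.integer(ceiling(stats::rlnorm(n, meanlog, sdlog))))

  ## -- infection schedule for true sepsis -----------------------------------
  p_co <- stats::plogis(
    stats::qlogis(ifelse(is_shock, cfg$p_community_onset$shock,
                         cfg$p_community_onset$nonshock)) +
      cfg$community_onset_logit_drift * yc)
  co <- is_sepsis & stats::runif(n) < p_co
  culture_day <- integer(n)
  abx_start <- integer(n)
  culture_day[co] <- sample(1:2, sum(co), replace = TRUE)
  abx_start[co] <- sample(1:2, sum(co), replace = TRUE)
  late <- is_sepsis & !co
  culture_day[late] <- 3L + as.integer(stats::rexp(sum(late), 1 / 6))
  culture_day[late] <- pmin(culture_day[late], 28L)
  delta <- sample(-2:2, sum(late), replace = TRUE,
                  prob = c(0.05, 0.15, 0.50, 0.20, 0.10))
  abx_start[late] <- pmax(1L, culture_day[late] + delta)
  abx_dur <- integer(n)
  abx_dur[is_sepsis] <- 4L + stats::rpois(sum(is_sepsis), 9)

  ## survivors must fit a 4-day course; the dead may be cut short (that is
  ## the death-exception pathway). Everyone needs culture/start inside the
  ## stay.
  need <- pmax(culture_day, abx_start +
                 ifelse(is_sepsis & !died, 3L, 0L))
  los <- pmax(los, ifelse(is_sepsis, need, 1L))

  ## -- dysfunction assignment for sepsis ------------------------------------
  ## shock: circulatory via vasopressor, plus extras; non-shock: one of
  ## respiratory / renal / code-based (+ optional second). Acute-RRT renal
  ## dysfunction is only assigned to patients not on maintenance dialysis.
  dys_resp <- logical(n); dys_renal <- logical(n); dys_code <- logical(n)
  ns <- which(is_sepsis & !is_shock)
  if (length(ns)) {
    pick <- sample(c("respiratory", "renal", "code"), length(ns),
                   replace = TRUE, prob = c(0.55, 0.12, 0.33))
    pick[pick == "renal" & maintenance_dialysis[ns]] <- "respiratory"
    dys_resp[ns] <- pick == "respiratory"
    dys_renal[ns] <- pick == "renal"
    dys_code[ns] <- pick == "code"
    second <- stats::runif(length(ns)) < 0.25
    add <- sample(c("respiratory", "code"), length(ns), replace = TRUE)
    dys_resp[ns] <- dys_resp[ns] | (second & add == "respiratory")
    dys_code[ns] <- dys_code[ns] | (second & add == "code")
  }
  sh <- which(is_shock)
  if (length(sh)) {
    dys_resp[sh] <- stats::runif(length(sh)) < 0.40
    dys_renal[sh] <- stats::runif(length(sh)) < 0.20 & !maintenance_dialysis[sh]
    dys_code[sh] <- stats::runif(length(sh)) < 0.20
  }
  code_cat <- rep(NA_character_, n)
  code_cat[dys_code] <- sample(names(GEN_DYSFUNCTION_CODE), sum(dys_code),
                               replace = TRUE)
  vaso_dur <- integer(n)
  vaso_dur[is_shock] <- 1L + stats::rpois(sum(is_shock), 1.8)
  hydro <- is_sepsis & stats::runif(n) <
    ifelse(is_shock, cfg$p_hydrocortisone$shock, cfg$p_hydrocortisone$nonshock)
  hydro_dur <- integer(n)
  hydro_dur[hydro] <- 1L + stats::rpois(sum(hydro), 2)
  focus <- rep(NA_character_, n)
  fc <- is_sepsis & stats::runif(n) < cfg$p_focus_coded
  focus[fc] <- sample(names(cfg$infection_focus_dist), sum(fc),
                      replace = TRUE, prob = cfg$infection_focus_dist)

  ## -- near-miss / background patterns among non-sepsis ---------------------
  nm <- rep("clean", n)
  neg <- which(!is_sepsis)
  if (length(neg)) {
    r <- cfg$near_miss_rates
    nm[neg] <- sample(c(names(r), "clean"), length(neg), replace = TRUE,
                      prob = c(r, 1 - sum(r)))
  }
  ## short courses and out-of-window courses are generated as survivors so
  ## the death exception can never rescue or truncate them
  force_alive <- nm %in% c("short_course", "out_of_window")
  died[force_alive] <- FALSE
  maintenance_dialysis[nm == "dialysis_rrt"] <- TRUE
  ## patterns need room inside the stay
  idx <- which(nm != "clean")
  if (length(idx)) {
    culture_day[idx] <- sample(1:5, length(idx), replace = TRUE)
    abx_start[idx] <- culture_day[idx]
    abx_start[nm == "out_of_window"] <- culture_day[nm == "out_of_window"] + 3L
    abx_dur[nm == "out_of_window"] <- 4L + stats::rpois(sum(nm == "out_of_window"), 5)
    abx_dur[nm == "short_course"] <- 3L
    abx_dur[nm == "dialysis_rrt"] <- 4L + stats::rpois(sum(nm == "dialysis_rrt"), 5)
    abx_dur[nm == "culture_no_abx"] <- 0L
    need_nm <- culture_day
    need_nm[nm == "out_of_window"] <- abx_start[nm == "out_of_window"] + 3L
    need_nm[nm == "short_course"] <- abx_start[nm == "short_course"] + 2L
    los[idx] <- pmax(los[idx], need_nm[idx])
  }
  bg_abx <- nm == "clean" & !is_sepsis & stats::runif(n) < cfg$p_background_abx
  bg_oxy <- !is_sepsis & stats::runif(n) < cfg$p_background_oxygen &
    nm %in% c("clean", "culture_no_abx", "out_of_window")

  death_day <- ifelse(died, los, NA_integer_)

  ## -- ICU day spans --------------------------------------------------------
  icu_len <- integer(n)
  icu_ml <- ifelse(is_shock, log(7), ifelse(is_sepsis, log(4), log(3)))
  icu_len[icu] <- pmax(1L, as.integer(round(
    stats::rlnorm(sum(icu), icu_ml[icu], 0.7))))
  icu_start <- ifelse(is_sepsis, pmin(pmax(1L, culture_day), los), 1L)
  icu_days <- rep("", n)
  w <- which(icu)
  icu_days[w] <- format_day_set(mapply(function(s, l, L)
    seq.int(min(s, L), min(s + l - 1L, L)),
    icu_start[w], icu_len[w], los[w], SIMPLIFY = FALSE))

  ## -- readmissions ---------------------------------------------------------
  patient_id <- sprintf("P%07d", seq_len(n))
  link_group <- function(ids) {
    k <- floor(cfg$readmission_rate * length(ids) / 2)
    if (k < 1) return(invisible(NULL))
    pick <- sample(ids, 2L * k)
    patient_id[pick[(k + 1):(2 * k)]] <<- patient_id[pick[1:k]]
  }
  link_group(which(is_sepsis))
  link_group(which(!is_sepsis))

  admissions <- data.table(
    admission_id = admission_id, patient_id = patient_id,
    admission_year = year, age = as.integer(age), sex = sex, bmi = bmi,
    los_days = los, died_in_hospital = died,
    death_day = as.integer(death_day), icu_days = icu_days,
    maintenance_dialysis = maintenance_dialysis)

  ## semicolon-joined true dysfunction labels (sepsis rows only)
  dys_chr <- character(n)
  idx_s <- which(is_sepsis)
  if (length(idx_s)) {
    m <- cbind(ifelse(is_shock[idx_s], "circulatory", NA),
               ifelse(dys_resp[idx_s], "respiratory", NA),
               ifelse(dys_renal[idx_s], "renal", NA),
               ifelse(dys_code[idx_s], code_cat[idx_s], NA))
    dys_chr[idx_s] <- apply(m, 1,
                            function(r) paste(r[!is.na(r)], collapse = ";"))
  }
  truth <- data.table(
    admission_id = admission_id,
    is_sepsis = is_sepsis, is_shock = is_shock,
    is_community_onset = is_sepsis & co,
    dysfunctions = dys_chr,
    truth_class = ifelse(is_shock, "shock",
                         ifelse(is_sepsis, "sepsis",
                                ifelse(nm == "clean", "clean_negative",
                                       paste0("near_miss_", nm)))))
  ## covariate flags used by ground-truth refits (parameter recovery)
  for (cm in colnames(comorb)) truth[[paste0("comorb_", cm)]] <- comorb[, cm]

  if (!events) {
    out <- new_claims(admissions,
                      data.table(admission_id = character(),
                                 icd10_code = character(),
                                 category_hint = character()),
                      data.table(admission_id = character(),
                                 event_type = character(),
                                 agent_id = character(), day = integer()))
    out$truth <- truth
    return(out)
  }

  ## -- diagnoses table ------------------------------------------------------
  dx_list <- list()
  for (cm in colnames(comorb)) {
    w <- which(comorb[, cm])
    if (length(w))
      dx_list[[cm]] <- data.table(admission_id = admission_id[w],
                                  icd10_code = GEN_COMORBIDITY_CODE[[cm]],
                                  category_hint = "comorbidity")
  }
  w <- which(dys_code)
  if (length(w))
    dx_list[["dysfx"]] <- data.table(
      admission_id = admission_id[w],
      icd10_code = GEN_DYSFUNCTION_CODE[code_cat[w]],
      category_hint = "organ_dysfunction")
  w <- which(!is.na(focus))
  if (length(w))
    dx_list[["focus"]] <- data.table(
      admission_id = admission_id[w],
      icd10_code = GEN_FOCUS_CODE[focus[w]],
      category_hint = "infection_focus")
  diagnoses <- data.table::rbindlist(dx_list)
  if (is.null(diagnoses) || !nrow(diagnoses))
    diagnoses <- data.table(admission_id = character(),
                            icd10_code = character(),
                            category_hint = character())

  ## -- events table ---------------------------------------------------------
  ## span_events expands per-admission (start, length) spans into one event
  ## row per day; s / len / agent are aligned with idx. Spans are clipped to
  ## the stay.
  ev <- list()
  span_events <- function(idx, type, s, len, agent = "") {
    if (!length(idx)) return(NULL)
    if (length(agent) == 1L) agent <- rep(agent, length(idx))
    s <- pmin(s, los[idx])
    len <- pmax(pmin(len, los[idx] - s + 1L), 0L)
    keep <- len > 0L
    idx <- idx[keep]; s <- s[keep]; len <- len[keep]; agent <- agent[keep]
    if (!length(idx)) return(NULL)
    data.table(admission_id = rep(admission_id[idx], len),
               event_type = type,
               agent_id = rep(agent, len),
               day = as.integer(sequence(len, from = s)))
  }
  has_culture <- is_sepsis | (nm != "clean" & !is_sepsis)
  w <- which(has_culture)
  ev$culture <- data.table(admission_id = admission_id[w],
                           event_type = "blood_culture", agent_id = "",
                           day = as.integer(pmin(culture_day[w], los[w])))
  ## antibiotic courses: one agent, with a switch to a second agent halfway
  ## through for ~30% of courses (agent switching must not break the
  ## consecutive-day run under the permissive default policy)
  abx_pool <- paste0("ABX", sprintf("%02d", 1:8))
  abx_idx <- which(abx_dur > 0L)
  agent1 <- sample(abx_pool, length(abx_idx), replace = TRUE)
  switch_course <- stats::runif(length(abx_idx)) < 0.30 & abx_dur[abx_idx] >= 6L
  half <- ifelse(switch_course, abx_dur[abx_idx] %/% 2L, abx_dur[abx_idx])
  ev$abx1 <- span_events(abx_idx, "iv_antibiotic", abx_start[abx_idx], half,
                         agent1)
  sw <- which(switch_course)
  if (length(sw)) {
    idx2 <- abx_idx[sw]
    other <- vapply(agent1[sw], function(a) setdiff(abx_pool, a)[1L],
                    character(1))
    ev$abx2 <- span_events(idx2, "iv_antibiotic",
                           abx_start[idx2] + half[sw],
                           abx_dur[idx2] - half[sw], other)
  }
  ## background antibiotics without culture (1-3 days, never qualifying)
  w <- which(bg_abx)
  if (length(w))
    ev$bg_abx <- span_events(w, "iv_antibiotic",
                             sample(1:3, length(w), replace = TRUE),
                             sample(1:3, length(w), replace = TRUE),
                             sample(abx_pool, length(w), replace = TRUE))
  ## vasopressors (shock)
  vp_idx <- which(vaso_dur > 0L)
  ev$vaso <- span_events(vp_idx, "vasopressor",
                         pmax(1L, culture_day[vp_idx]), vaso_dur[vp_idx],
                         sample(c("NORAD", "ADR", "DOPA", "VASOP"),
                                length(vp_idx), replace = TRUE))
  ## respiratory support: ventilation for ~30%, oxygen otherwise
  rs <- which(dys_resp)
  if (length(rs)) {
    vent <- stats::runif(length(rs)) < 0.30
    rd <- 1L + stats::rpois(length(rs), 3)
    ev$vent <- span_events(rs[vent], "mechanical_ventilation",
                           pmax(1L, culture_day[rs[vent]]), rd[vent])
    ev$oxy <- span_events(rs[!vent], "oxygen_therapy",
                          pmax(1L, culture_day[rs[!vent]]), rd[!vent])
  }
  ## acute RRT (true renal dysfunction) and maintenance-dialysis RRT near-miss
  rr <- which(dys_renal | (nm == "dialysis_rrt" & !is_sepsis))
  ev$rrt <- span_events(rr, "renal_replacement",
                        pmax(1L, culture_day[rr]), rep(3L, length(rr)))
  hy <- which(hydro)
  ev$hydro <- span_events(hy, "hydrocortisone",
                          pmax(1L, culture_day[hy]), hydro_dur[hy])
  w <- which(bg_oxy)
  if (length(w))
    ev$bg_oxy <- span_events(w, "oxygen_therapy", rep(1L, length(w)),
                             rep(2L, length(w)))
  events_dt <- data.table::rbindlist(ev[!vapply(ev, is.null, logical(1))])
  setorder(events_dt, admission_id, day, event_type, agent_id)

  out <- new_claims(admissions, diagnoses, events_dt)
  out$truth <- truth
  out
}
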