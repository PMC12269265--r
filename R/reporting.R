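#' Analysis plan for the reporting pipeline
#'
#' @param age_bins Breaks partitioning adult ages; default the clinically
#'   standard 18-64, 65-74, 75-84, ≥85 bands.
#' @param subgroup_axes Subset of `c("age", "sex", "icu_shock")`.
#' @param alpha Two-sided significance level.
#' @return A list with class `analysis_plan`. Deduplication policy is fixed
#'   by outcome: patient-level for mortality and deaths per 1,000
#'   inpatients, admission-level for proportions and length of stay.
#' @export
analysis_plan <- function(age_bins = c(18, 65, 75, 85, Inf),
                          subgroup_axes = c("age", "sex", "icu_shock"),
                          alpha = 0.05) {
  stopifnot(age_bins[1] == 18, is.infinite(age_bins[length(age_bins)]))
  subgroup_axes <- match.arg(subgroup_axes, several.ok = TRUE)
  structure(list(age_bins = age_bins, subgroup_axes = subgroup_axes,
                 alpha = alpha,
                 dedup_policy = c(mortality = "patient",
                                  deaths_per_1000 = "patient",
                                  proportion = "admission",
                                  los = "admission")),
            class = "analysis_plan")
}

age_band <- function(age, breaks) {
  labs <- paste0(utils::head(breaks, -1), "-",
                 ifelse(is.finite(breaks[-1]), breaks[-1] - 1, ""))
  labs[length(labs)] <- paste0(breaks[length(breaks) - 1], "+")
  cut(age, breaks = breaks, labels = labs, right = FALSE)
}

#' Recompute published surveillance ratios from packaged counts
#'
#' Loads the packaged constants file of printed counts from nationwide
#' Japanese DPC sepsis surveillance (2010-2020) — cohort sizes, deaths,
#' ICU admissions, and similar — and recomputes every ratio with the
#' package's own [proportion()] and [deaths_per_1000()] operations, applying
#' the display rounding convention (percentages to the printed number of
#' decimals, rates to 2).
#'
#' @param path CSV of counts; defaults to the packaged file.
#' @return data.table: quantity, numerator, denominator, value (full
#'   precision on the display scale) and display (rounded).
#' @export
check_arithmetic <- function(path = system.file("extdata",
                                                "published_counts.csv",
                                                package = "sepsisclaims")) {
  counts <- fread(path)
  value <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    value[i] <- if (counts$scale[i] == "per1000")
      deaths_per_1000(counts$numerator[i], counts$denominator[i])
    else 100 * proportion(counts$numerator[i],
                          counts$denominator[i])$proportion
  }
  counts[, value := value]
  counts[, display := round(value, digits)]
  counts[]
}

fmt_n_pct <- function(k, n) sprintf("%d (%.1f)", k, 100 * k / max(n, 1))
fmt_mean_sd <- function(x) sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
fmt_med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  sprintf("%g (%g-%g)", q[2], q[1], q[3])
}

comorbidity_flags <- function(episodes, diagnoses,
                              code_lists = default_code_lists()) {
  dx <- as.data.table(diagnoses)
  out <- as.data.table(episodes)[, list(admission_id)]
  for (cm in names(code_lists$comorbidity)) {
    hit <- unique(dx$admission_id[icd10_match(dx$icd10_code,
                                              code_lists$comorbidity[[cm]],
                                              code_lists$matching)])
    data.table::set(out, j = cm, value = out$admission_id %in% hit)
  }
  out
}

#' Cohort characteristics table (shock vs non-shock)
#'
#' Builds the standard baseline-characteristics comparison among sepsis
#' admissions: demographics, community onset, comorbidities, antibiotic
#' timing and duration, vasopressor and hydrocortisone use — each with
#' whole-cohort, shock and non-shock columns and the appropriate two-group
#' test (chi-square for proportions, Mann-Whitney for skewed continuous
#' variables).
#'
#' @param episodes Episode table from [classify_admissions()] (all
#'   admissions; the sepsis subset is selected internally).
#' @param diagnoses Diagnoses table (for comorbidity categories).
#' @param code_lists Code-list configuration.
#' @return data.table: variable, statistic, overall, shock, nonshock,
#'   p_value.
#' @export
build_table1 <- function(episodes, diagnoses,
                         code_lists = default_code_lists()) {
  ep <- copy(as.data.table(episodes))[is_sepsis == TRUE]
  if (!nrow(ep)) stop("build_table1: no sepsis episodes")
  sh <- ep[is_shock == TRUE]
  ns <- ep[is_shock == FALSE]
  empty_shock <- nrow(sh) == 0L
  rows <- list()
  add <- function(variable, statistic, overall, shock, nonshock, p = NA_real_)
    rows[[length(rows) + 1L]] <<- data.table(
      variable = variable, statistic = statistic, overall = overall,
      shock = shock, nonshock = nonshock, p_value = p)

  add("n", "count", as.character(nrow(ep)), as.character(nrow(sh)),
      as.character(nrow(ns)))
  cat_row <- function(name, flag) {
    k <- c(sum(ep[[flag]]), sum(sh[[flag]]), sum(ns[[flag]]))
    p <- if (empty_shock || nrow(ns) == 0) NA_real_ else
      compare_groups("categorical", c(k[2], nrow(sh)), c(k[3], nrow(ns)))$p_value
    add(name, "n_pct", fmt_n_pct(k[1], nrow(ep)), fmt_n_pct(k[2], nrow(sh)),
        fmt_n_pct(k[3], nrow(ns)), p)
  }
  rank_row <- function(name, col, na_ok = FALSE) {
    v <- ep[[col]]; vs <- sh[[col]]; vn <- ns[[col]]
    if (na_ok) { v <- v[!is.na(v)]; vs <- vs[!is.na(vs)]; vn <- vn[!is.na(vn)] }
    p <- if (length(vs) && length(vn))
      compare_groups("rank", vs, vn)$p_value else NA_real_
    add(name, "median_iqr", fmt_med_iqr(v),
        if (length(vs)) fmt_med_iqr(vs) else "-",
        if (length(vn)) fmt_med_iqr(vn) else "-", p)
  }
  rank_row("age_years", "age")
  ep[, female := sex == "female"]
  sh <- ep[is_shock == TRUE]; ns <- ep[is_shock == FALSE]
  cat_row("female", "female")
  rank_row("bmi", "bmi", na_ok = TRUE)
  cat_row("community_onset", "is_community_onset")

  cm <- comorbidity_flags(ep, diagnoses, code_lists)
  for (nm in setdiff(names(cm), "admission_id"))
    data.table::set(ep, j = paste0("cm_", nm),
                    value = cm[[nm]][match(ep$admission_id,
                                           cm$admission_id)])
  sh <- ep[is_shock == TRUE]; ns <- ep[is_shock == FALSE]
  for (nm in setdiff(names(cm), "admission_id"))
    cat_row(paste0("comorbidity_", nm), paste0("cm_", nm))

  rank_row("antibiotic_start_day", "antibiotic_start_day")
  rank_row("antibiotic_days", "antibiotic_days")
  if (!empty_shock)
    add("vasopressor_days", "median_iqr", "-",
        fmt_med_iqr(sh$vasopressor_days), "-")
  ep[, hydro_use := hydrocortisone_days > 0L]
  sh <- ep[is_shock == TRUE]; ns <- ep[is_shock == FALSE]
  cat_row("hydrocortisone_use", "hydro_use")
  out <- data.table::rbindlist(rows)
  if (empty_shock) attr(out, "empty_column") <- "shock"
  out
}

#' Clinical outcomes table (shock vs non-shock)
#'
#' In-hospital mortality (patient-level, deduplicated), deaths per 1,000
#' inpatients (deduplicated sepsis deaths over all screened admissions),
#' hospital LOS (admission-level), ICU admission and ICU LOS, with the
#' shock vs non-shock comparison test for each.
#'
#' @param episodes Episode table over all screened admissions.
#' @return data.table: outcome, statistic, overall, shock, nonshock,
#'   p_value.
#' @export
build_table2 <- function(episodes) {
  ep <- as.data.table(episodes)
  n_screened <- nrow(ep)
  sep <- ep[is_sepsis == TRUE]
  dd <- deduplicate(ep)
  rows <- list()
  add <- function(outcome, statistic, overall, shock, nonshock,
                  p = NA_real_)
    rows[[length(rows) + 1L]] <<- data.table(
      outcome = outcome, statistic = statistic, overall = overall,
      shock = shock, nonshock = nonshock, p_value = p)

  mort <- function(d) c(sum(d$died_in_hospital), nrow(d))
  m_all <- mort(dd); m_sh <- mort(dd[is_shock == TRUE])
  m_ns <- mort(dd[is_shock == FALSE])
  p <- if (m_sh[2] > 0 && m_ns[2] > 0)
    compare_groups("categorical", m_sh, m_ns)$p_value else NA_real_
  add("inhospital_mortality", "n_pct", fmt_n_pct(m_all[1], m_all[2]),
      fmt_n_pct(m_sh[1], m_sh[2]), fmt_n_pct(m_ns[1], m_ns[2]), p)
  add("deaths_per_1000_inpatients", "rate",
      sprintf("%.2f", deaths_per_1000(m_all[1], n_screened)),
      sprintf("%.2f", deaths_per_1000(m_sh[1], n_screened)),
      sprintf("%.2f", deaths_per_1000(m_ns[1], n_screened)))

  sh <- sep[is_shock == TRUE]; ns <- sep[is_shock == FALSE]
  p <- if (nrow(sh) && nrow(ns))
    compare_groups("rank", sh$los_days, ns$los_days)$p_value else NA_real_
  add("hospital_los", "mean_sd", fmt_mean_sd(sep$los_days),
      if (nrow(sh)) fmt_mean_sd(sh$los_days) else "-",
      if (nrow(ns)) fmt_mean_sd(ns$los_days) else "-", p)
  add("hospital_los", "median_iqr", fmt_med_iqr(sep$los_days),
      if (nrow(sh)) fmt_med_iqr(sh$los_days) else "-",
      if (nrow(ns)) fmt_med_iqr(ns$los_days) else "-")
  k <- c(sum(sep$icu_admission), sum(sh$icu_admission), sum(ns$icu_admission))
  p <- if (nrow(sh) && nrow(ns))
    compare_groups("categorical", c(k[2], nrow(sh)),
                   c(k[3], nrow(ns)))$p_value else NA_real_
  add("icu_admission", "n_pct", fmt_n_pct(k[1], nrow(sep)),
      fmt_n_pct(k[2], nrow(sh)), fmt_n_pct(k[3], nrow(ns)), p)
  icu <- sep[icu_admission == TRUE]
  if (nrow(icu)) {
    ish <- icu[is_shock == TRUE]; ins <- icu[is_shock == FALSE]
    p <- if (nrow(ish) && nrow(ins))
      compare_groups("rank", ish$icu_los, ins$icu_los)$p_value else NA_real_
    add("icu_los", "median_iqr", fmt_med_iqr(icu$icu_los),
        if (nrow(ish)) fmt_med_iqr(ish$icu_los) else "-",
        if (nrow(ins)) fmt_med_iqr(ins$icu_los) else "-", p)
  }
  data.table::rbindlist(rows)
}

wilson_cols <- function(dt) {
  if (!nrow(dt)) return(dt)
  ci <- mapply(function(k, n) proportion(k, n)$ci95, dt$events, dt$total)
  dt[, value := 100 * events / total]
  dt[, ci_low := 100 * ci[1, ]]
  dt[, ci_high := 100 * ci[2, ]]
  dt[]
}

#' Yearly trend tables with trend tests
#'
#' For each outcome and subgroup: per-year values with 95% CIs plus the
#' matching trend test — Cochran-Armitage for categorical outcomes
#' (mortality, sepsis proportion among inpatients), linear regression for
#' continuous ones (deaths per 1,000 inpatients, mean LOS, survivor- and
#' non-survivor-stratified LOS). Mortality and deaths per 1,000 use the
#' deduplicated patient-level cohort (each patient assigned to the year of
#' the kept admission); proportions and LOS use all admissions. Subgroup-
#' years with an empty denominator are dropped from that subgroup's test
#' with a warning.
#'
#' @param episodes Episode table over all screened admissions.
#' @param plan An [analysis_plan()].
#' @return A list of data.tables: `mortality`, `sepsis_proportion`,
#'   `deaths_per_1000`, `mean_los`, `los_by_survival`, subgroup mortality
#'   tables per requested axis, and `tests` (one row per computed trend
#'   test).
#' @export
build_trends <- function(episodes, plan = analysis_plan()) {
  ep <- as.data.table(episodes)
  if (length(unique(ep$admission_year)) < 2)
    stop("build_trends: need at least 2 years")
  screened <- ep[, list(total = .N), by = "admission_year"]
  dd <- copy(deduplicate(ep))
  dd[, group := ifelse(is_shock, "shock", "nonshock")]
  sep <- copy(ep[is_sepsis == TRUE])
  sep[, group := ifelse(is_shock, "shock", "nonshock")]
  tests <- list()
  note_test <- function(outcome, group, tt)
    tests[[length(tests) + 1L]] <<- data.table(
      outcome = outcome, group = group, statistic = tt$statistic,
      slope = if (is.null(tt$slope)) NA_real_ else tt$slope,
      r_squared = if (is.null(tt$r_squared)) NA_real_ else tt$r_squared,
      p_value = tt$p_value, direction = tt$direction)

  ca_by_group <- function(dt, outcome) {
    out <- list()
    for (g in unique(dt$group)) {
      sub <- dt[group == g][order(year)]
      bad <- sub$total == 0
      if (any(bad)) {
        warning(outcome, " [", g, "]: dropping ", sum(bad),
                " year(s) with empty denominator")
        sub <- sub[!bad]
      }
      if (nrow(sub) >= 2 && sum(sub$events) > 0 &&
          sum(sub$events) < sum(sub$total))
        note_test(outcome, g, cochran_armitage(sub$year, sub$events,
                                               sub$total))
      out[[g]] <- wilson_cols(sub)
    }
    data.table::rbindlist(out)
  }

  ## mortality among sepsis patients (deduplicated), by shock group
  mort <- dd[, list(events = sum(died_in_hospital), total = .N),
             by = list(group, year = admission_year)]
  mortality <- ca_by_group(mort, "inhospital_mortality")

  ## sepsis/shock proportion among all inpatient admissions
  prop <- sep[, list(events = .N), by = list(group, year = admission_year)]
  prop <- merge(prop, screened[, list(year = admission_year, total)],
                by = "year")
  sepsis_proportion <- ca_by_group(prop, "sepsis_proportion")

  ## deaths per 1,000 inpatients: deduplicated deaths over screened
  dp <- dd[died_in_hospital == TRUE, list(deaths = .N),
           by = list(group, year = admission_year)]
  grid <- data.table::CJ(group = unique(dd$group),
                         year = screened$admission_year)
  dp <- merge(grid, dp, by = c("group", "year"), all.x = TRUE)
  dp[is.na(deaths), deaths := 0L]
  dp <- merge(dp, screened[, list(year = admission_year, total)],
              by = "year")
  dp[, value := mapply(deaths_per_1000, deaths, total)]
  for (g in unique(dp$group)) {
    sub <- dp[group == g][order(year)]
    if (nrow(sub) >= 3)
      note_test("deaths_per_1000", g, linear_trend(sub$year, sub$value))
  }

  ## mean LOS per year (all sepsis admissions), overall and by survival
  mlos <- sep[, list(value = mean(los_days), n = .N),
              by = list(group, year = admission_year)]
  for (g in unique(mlos$group)) {
    sub <- mlos[group == g][order(year)]
    if (nrow(sub) >= 3)
      note_test("mean_los", g, linear_trend(sub$year, sub$value))
  }
  slos <- sep[, list(value = mean(los_days), n = .N),
              by = list(group, survivor = !died_in_hospital,
                        year = admission_year)]
  for (g in unique(slos$group)) for (sv in c(TRUE, FALSE)) {
    sub <- slos[group == g & survivor == sv][order(year)]
    if (nrow(sub) >= 3)
      note_test(paste0("mean_los_", if (sv) "survivor" else "non_survivor"),
                g, linear_trend(sub$year, sub$value))
  }

  out <- list(mortality = mortality, sepsis_proportion = sepsis_proportion,
              deaths_per_1000 = dp[order(group, year)],
              mean_los = mlos[order(group, year)],
              los_by_survival = slos[order(group, survivor, year)])

  ## subgroup mortality trends
  if ("age" %in% plan$subgroup_axes) {
    dda <- copy(dd)[, band := age_band(age, plan$age_bins)]
    am <- dda[, list(events = sum(died_in_hospital), total = .N),
              by = list(group = paste(group, band, sep = ":"),
                        year = admission_year)]
    out$mortality_by_age <- ca_by_group(am, "mortality_by_age")
  }
  if ("sex" %in% plan$subgroup_axes) {
    sm <- dd[, list(events = sum(died_in_hospital), total = .N),
             by = list(group = paste(group, sex, sep = ":"),
                       year = admission_year)]
    out$mortality_by_sex <- ca_by_group(sm, "mortality_by_sex")
  }
  if ("icu_shock" %in% plan$subgroup_axes) {
    im <- dd[, list(events = sum(died_in_hospital), total = .N),
             by = list(group = paste(group,
                                     ifelse(icu_admission, "icu", "ward"),
                                     sep = ":"),
                       year = admission_year)]
    out$mortality_by_icu <- ca_by_group(im, "mortality_by_icu")
  }
  out$tests <- data.table::rbindlist(tests)
  out
}

#' Adjusted secular-trend mortality model
#'
#' Multivariable IRLS logistic regression for in-hospital death among
#' deduplicated sepsis patients, overall and stratified by shock status.
#' Year of admission enters as a continuous covariate, so its odds ratio is
#' the adjusted OR per admission year. Default covariates: year, age, sex,
#' BMI (complete case), community onset, hospital day of antibiotic
#' initiation, ICU admission, hydrocortisone use, and the comorbidity
#' categories.
#'
#' @param episodes Episode table over all screened admissions.
#' @param diagnoses Diagnoses table.
#' @param code_lists Code-list configuration.
#' @return data.table of coefficient rows with a `stratum` column
#'   (`whole`, `shock`, `nonshock`).
#' @export
adjusted_mortality_model <- function(episodes, diagnoses,
                                     code_lists = default_code_lists()) {
  dd <- deduplicate(as.data.table(episodes))
  cm <- comorbidity_flags(dd, diagnoses, code_lists)
  dd <- merge(dd, cm, by = "admission_id")
  fit_stratum <- function(d, label) {
    cov <- data.frame(
      year = d$admission_year, age = d$age,
      male = d$sex == "male", bmi = d$bmi,
      community_onset = d$is_community_onset,
      antibiotic_start_day = d$antibiotic_start_day,
      icu = d$icu_admission, hydrocortisone = d$hydrocortisone_days > 0)
    for (nm in setdiff(names(cm), "admission_id")) cov[[nm]] <- d[[nm]]
    ## drop constant covariates, and sparse binary covariates whose
    ## outcome cross-tabulation has an empty cell (they quasi-separate
    ## small cohorts and carry no stable effect estimate)
    y <- d$died_in_hospital
    usable <- vapply(cov, function(v) {
      u <- unique(v[!is.na(v)])
      if (length(u) < 2) return(FALSE)
      if (is.logical(v) || length(u) == 2)
        return(all(table(v, y) > 0))
      TRUE
    }, logical(1))
    cov <- cov[, usable, drop = FALSE]
    fit <- logistic_fit(y, cov)
    out <- copy(fit$coefficients)
    out[, stratum := label]
    out
  }
  res <- list(fit_stratum(dd, "whole"))
  if (nrow(dd[is_shock == TRUE]) > 50)
    res <- c(res, list(fit_stratum(dd[is_shock == TRUE], "shock")))
  if (nrow(dd[is_shock == FALSE]) > 50)
    res <- c(res, list(fit_stratum(dd[is_shock == FALSE], "nonshock")))
  data.table::rbindlist(res)
}

#' Run the full surveillance pipeline
#'
#' simulate (or load) claims → validate → phenotype → characteristics,
#' outcome, trend and adjusted-OR tables, with a reproducibility manifest
#' (seed, config hash, package version, stage row counts). Identical
#' config and seed reproduce the bundle exactly.
#'
#' @param config A [sim_config()] (simulation mode), or a directory
#'   containing `admissions.csv` / `diagnoses.csv` / `events.csv` (table
#'   input mode).
#' @param code_lists Code-list configuration.
#' @param plan An [analysis_plan()].
#' @return A list with class `report_bundle`: `table1`, `table2`, `trends`,
#'   `adjusted_or`, `episodes`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(),
                         code_lists = default_code_lists(),
                         plan = analysis_plan()) {
  stage <- "simulate"
  result <- tryCatch({
    if (inherits(config, "sim_config")) {
      claims <- simulate_claims(config)
    } else {
      stage <- "read"
      claims <- read_claims(file.path(config, "admissions.csv"),
                            file.path(config, "diagnoses.csv"),
                            file.path(config, "events.csv"))
    }
    stage <- "filter"
    claims$admissions <- filter_cohort(claims$admissions, quiet = TRUE)
    stage <- "phenotype"
    episodes <- classify_admissions(claims, code_lists)
    stage <- "analyze"
    table1 <- build_table1(episodes, claims$diagnoses, code_lists)
    table2 <- build_table2(episodes)
    trends <- build_trends(episodes, plan)
    adjusted <- adjusted_mortality_model(episodes, claims$diagnoses,
                                         code_lists)
    stage <- "report"
    manifest <- list(
      seed = if (inherits(config, "sim_config")) config$seed else NA,
      config_hash = hash_object(unclass(config)),
      package_version = as.character(utils::packageVersion("sepsisclaims")),
      n_admissions = nrow(claims$admissions),
      n_sepsis = sum(episodes$is_sepsis),
      n_shock = sum(episodes$is_shock),
      n_patients_dedup = nrow(deduplicate(episodes)))
    structure(list(table1 = table1, table2 = table2, trends = trends,
                   adjusted_or = adjusted, episodes = episodes,
                   manifest = manifest),
              class = "report_bundle")
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  result
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  ## version-pinned serialization keeps the hash stable across sessions
  con <- file(f, "wb")
  serialize(x, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

#' Write a report bundle to CSV files
#'
#' Deterministic writer: rerunning the same bundle produces byte-identical
#' files. The manifest is written as YAML.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(bundle$table1, file.path(dir, "table1_characteristics.csv"))
  write_table(bundle$table2, file.path(dir, "table2_outcomes.csv"))
  for (nm in names(bundle$trends))
    write_table(bundle$trends[[nm]], file.path(dir, paste0("trend_", nm,
                                                           ".csv")))
  write_table(bundle$adjusted_or, file.path(dir, "adjusted_or.csv"))
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
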