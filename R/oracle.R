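#' Brute-force reference phenotyper
#'
#' Literal, exhaustive evaluation of the case definitions, intended for
#' testing [classify()] on small admissions (los_days ≤ 60): builds the full
#' day-by-agent antibiotic administration table, enumerates *every*
#' (blood-culture event, antibiotic event) pair, and checks each rule
#' day by day — the ±2-day window, the agent's new-initiation lookback, the
#' 4-consecutive-day coverage (or death before the 4th day with antibiotics
#' through death), dysfunction categories, vasopressor-defined shock, and
#' the 48-hour community-onset rule. Shares no code with the production
#' path.
#'
#' @inheritParams classify
#' @return A one-row data.table with the same columns as [classify()].
#' @export
classify_oracle <- function(admission, diagnoses, events,
                            code_lists = default_code_lists(), lookback = 2L,
                            policy = "permissive") {
  ev <- as.data.frame(events)
  dx <- as.data.frame(diagnoses)
  los <- admission$los_days
  stopifnot(los <= 60)
  died <- isTRUE(admission$died_in_hospital)
  death_day <- if (died) admission$death_day else NA

  abx <- ev[ev$event_type == "iv_antibiotic" &
              ev$agent_id %in% code_lists$antibiotics, , drop = FALSE]
  agents <- unique(abx$agent_id)
  ## day x agent administration grid
  grid <- matrix(FALSE, nrow = los, ncol = length(agents),
                 dimnames = list(NULL, agents))
  for (k in seq_len(nrow(abx))) grid[abx$day[k], abx$agent_id[k]] <- TRUE

  cultures <- ev[ev$event_type == "blood_culture", , drop = FALSE]
  qualifying <- list()
  for (ci in seq_len(nrow(cultures))) {
    for (ai in seq_len(nrow(abx))) {
      cd <- cultures$day[ci]
      s <- abx$day[ai]
      a <- abx$agent_id[ai]
      if (abs(s - cd) > 2 || s < 1) next
      ## newly initiated: agent absent on the lookback days before s
      prior <- (s - lookback):(s - 1)
      prior <- prior[prior >= 1 & prior <= los]
      if (length(prior) && any(grid[prior, a])) next
      covered_on <- function(d) {
        if (d < 1 || d > los) return(FALSE)
        if (policy == "strict") grid[d, a] else any(grid[d, ])
      }
      four <- all(vapply(s:(s + 3), covered_on, logical(1)))
      death_ok <- FALSE
      if (!four && died && !is.na(death_day) && death_day < s + 3 &&
          death_day >= s)
        death_ok <- all(vapply(s:death_day, covered_on, logical(1)))
      if (four || death_ok)
        qualifying[[length(qualifying) + 1L]] <-
          data.frame(cd = cd, s = s, agent = a)
    }
  }

  infection <- NULL
  if (length(qualifying)) {
    q <- unique(do.call(rbind, qualifying))
    q <- q[order(q$cd, q$s, q$agent), , drop = FALSE]
    cd <- q$cd[1]; s <- q$s[1]; a <- q$agent[1]
    r <- 0L
    repeat {
      d <- s + r
      ok <- d >= 1 && d <= los &&
        (if (policy == "strict") grid[d, a] else any(grid[d, ]))
      if (!ok) break
      r <- r + 1L
    }
    infection <- list(culture_day = as.integer(cd),
                      antibiotic_start_day = as.integer(s),
                      qualifying_days = as.integer(r),
                      qualified_by_death = r < 4L)
  }

  dys <- character(0)
  if (any(ev$event_type == "vasopressor")) dys <- c(dys, "circulatory")
  if (any(ev$event_type %in% c("mechanical_ventilation", "oxygen_therapy")))
    dys <- c(dys, "respiratory")
  if (any(ev$event_type == "renal_replacement") &&
      !isTRUE(admission$maintenance_dialysis))
    dys <- c(dys, "renal")
  for (cat in c("hepatic", "thrombocytopenia", "coagulopathy", "acidosis")) {
    hit <- FALSE
    for (code in dx$icd10_code)
      for (p in code_lists$dysfunction[[cat]])
        if (if (code_lists$matching == "exact") code == p
            else substr(code, 1, nchar(p)) == p) hit <- TRUE
    if (hit) dys <- c(dys, cat)
  }
  episode_row(admission, infection, dys, as.data.table(ev))
}
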