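#' Proportion with Wilson 95% confidence interval
#'
#' Point estimate `numerator/denominator` with the Wilson score interval
#' (the default because it behaves at 0/n and n/n without degenerating;
#' a Wald interval is available via `method`).
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @param conf Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"wald"`.
#' @return A list `(numerator, denominator, proportion, ci95 = c(low,
#'   high))` with class `proportion_estimate`.
#' @export
proportion <- function(numerator, denominator, conf = 0.95,
                       method = c("wilson", "wald")) {
  method <- match.arg(method)
  if (denominator <= 0) stop("proportion: denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stop("proportion: numerator must lie in [0, denominator]")
  p <- numerator / denominator
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n <- denominator
  if (method == "wilson") {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    ci <- c(max(0, centre - half), min(1, centre + half))
  } else {
    half <- z * sqrt(p * (1 - p) / n)
    ci <- c(max(0, p - half), min(1, p + half))
  }
  structure(list(numerator = numerator, denominator = denominator,
                 proportion = p, ci95 = ci),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d / %d = %.4f (95%% CI %.4f-%.4f)\n", x$numerator,
              x$denominator, x$proportion, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Deaths per 1,000 inpatients
#'
#' Population-burden rate: deduplicated sepsis deaths over *all* screened
#' inpatient admissions, times 1,000. Distinct from case fatality. Returned
#' at full precision; the display convention rounds to 2 decimals.
#'
#' @param deaths,inpatients Counts with `deaths <= inpatients`,
#'   `inpatients > 0`.
#' @return The rate (numeric scalar).
#' @export
deaths_per_1000 <- function(deaths, inpatients) {
  if (inpatients <= 0) stop("deaths_per_1000: inpatients must be positive")
  if (deaths < 0 || deaths > inpatients)
    stop("deaths_per_1000: deaths must lie in [0, inpatients]")
  deaths / inpatients * 1000
}

#' Length-of-stay summary, overall and by survival stratum
#'
#' Mean (SD) and median (IQR); quartiles by linear interpolation between
#' order statistics (`stats::quantile` type 7) — stated because IQR
#' conventions differ between software.
#'
#' @param values Positive stay lengths (days).
#' @param survived Logical vector (TRUE = survivor), same length; optional.
#' @return A data.table with rows `overall` and, when `survived` is given,
#'   `survivor` / `non_survivor`; columns n, mean, sd, median, q1, q3.
#' @export
los_summary <- function(values, survived = NULL) {
  if (!length(values)) stop("los_summary: empty input")
  one <- function(v, label) {
    if (!length(v))
      return(data.table(stratum = label, n = 0L, mean = NA_real_,
                        sd = NA_real_, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.table(stratum = label, n = length(v), mean = mean(v),
               sd = stats::sd(v), median = q[2], q1 = q[1], q3 = q[3])
  }
  out <- one(values, "overall")
  if (!is.null(survived)) {
    stopifnot(length(survived) == length(values))
    out <- rbind(out, one(values[survived], "survivor"),
                 one(values[!survived], "non_survivor"))
  }
  out
}

#' Cochran-Armitage trend test
#'
#' Score test for a monotone trend in binomial proportions across ordered
#' categories (calendar years). With scores \eqn{s_i} (year indices), events
#' \eqn{e_i}, totals \eqn{n_i}, pooled proportion \eqn{\bar p} and
#' total-weighted mean score \eqn{\bar s}:
#' \deqn{Z = \sum_i e_i (s_i - \bar s) /
#'       \sqrt{\bar p (1-\bar p) \sum_i n_i (s_i - \bar s)^2}}
#' Two-sided p from the standard normal; Z is invariant under affine
#' rescaling of the scores.
#'
#' @param years Ordered integer scores (e.g. calendar years).
#' @param events,totals Per-year event and denominator counts.
#' @return A list `(statistic, p_value, direction)` with class
#'   `trend_test`; `direction` is `"increasing"`, `"decreasing"` or
#'   `"flat"`.
#' @export
cochran_armitage <- function(years, events, totals) {
  stopifnot(length(years) == length(events), length(events) == length(totals))
  if (length(years) < 2) stop("cochran_armitage: need at least 2 years")
  if (any(totals <= 0)) stop("cochran_armitage: totals must be positive")
  if (any(events < 0 | events > totals))
    stop("cochran_armitage: events must lie in [0, totals]")
  pbar <- sum(events) / sum(totals)
  if (pbar <= 0 || pbar >= 1)
    stop("cochran_armitage: degenerate input (pooled proportion 0 or 1)")
  sbar <- sum(totals * years) / sum(totals)
  num <- sum(events * (years - sbar))
  den <- sqrt(pbar * (1 - pbar) * sum(totals * (years - sbar)^2))
  z <- num / den
  structure(list(statistic = z,
                 slope = NULL, r_squared = NULL,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 direction = if (z > 0) "increasing"
                             else if (z < 0) "decreasing" else "flat"),
            class = "trend_test")
}

#' Linear trend of a continuous yearly series
#'
#' Ordinary least squares of the value on calendar year (unweighted; yearly
#' summaries enter with equal weight, matching the slope/R-squared
#' presentation style of surveillance reports). Returns the slope, R², and
#' the two-sided t-test p-value on the slope.
#'
#' @param years Calendar years (≥ 3 distinct values).
#' @param values Per-year values.
#' @param weights Optional per-year weights (e.g. admission counts).
#' @return A list `(statistic, slope, r_squared, p_value, direction)` with
#'   class `trend_test`; `statistic` is the slope's t value.
#' @export
linear_trend <- function(years, values, weights = NULL) {
  stopifnot(length(years) == length(values))
  if (length(years) < 3) stop("linear_trend: need at least 3 points")
  if (length(unique(years)) < 2)
    stop("linear_trend: singular design (all years identical)")
  if (stats::var(values) == 0)
    return(structure(list(statistic = 0, slope = 0, r_squared = 0,
                          p_value = 1, direction = "flat"),
                     class = "trend_test"))
  fit <- if (is.null(weights)) stats::lm(values ~ years)
         else stats::lm(values ~ years, weights = weights)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  tval <- sm$coefficients[2, "t value"]
  p <- sm$coefficients[2, "Pr(>|t|)"]
  structure(list(statistic = unname(tval), slope = slope,
                 r_squared = sm$r.squared, p_value = unname(p),
                 direction = if (slope > 0) "increasing"
                             else if (slope < 0) "decreasing" else "flat"),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  if (is.null(x$slope))
    cat(sprintf("Cochran-Armitage Z = %.3f, p = %.3g (%s)\n", x$statistic,
                x$p_value, x$direction))
  else
    cat(sprintf("slope = %.4f, R^2 = %.3f, t = %.3f, p = %.3g (%s)\n",
                x$slope, x$r_squared, x$statistic, x$p_value, x$direction))
  invisible(x)
}

#' Two-group comparisons for cohort tables
#'
#' Chi-square test without continuity correction for categorical variables
#' (appropriate at claims-scale counts; Yates' correction available via
#' `correct`), Welch's t-test for means, and the Mann-Whitney U test for
#' skewed continuous variables (normal approximation with tie correction;
#' the exact method for n ≤ 20 per group without ties).
#'
#' @param type `"categorical"`, `"mean"`, or `"rank"`.
#' @param a,b For `"categorical"`: `c(events, total)` per group; otherwise
#'   the raw values per group.
#' @param correct Continuity correction for the chi-square test.
#' @return A list `(statistic, p_value, test)`.
#' @export
compare_groups <- function(type = c("categorical", "mean", "rank"), a, b,
                           correct = FALSE) {
  type <- match.arg(type)
  if (type == "categorical") {
    tab <- rbind(c(a[1], a[2] - a[1]), c(b[1], b[2] - b[1]))
    if (any(tab < 0)) stop("compare_groups: events must not exceed totals")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1))
      warning("compare_groups: expected cell count below 1")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "chi-square")
  } else if (type == "mean") {
    ht <- stats::t.test(a, b)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "welch-t")
  } else {
    exact <- length(a) <= 20 && length(b) <= 20 &&
      !anyDuplicated(c(a, b))
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "mann-whitney")
  }
}
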