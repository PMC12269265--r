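test_that("proportions reproduce printed surveillance percentages", {
  expect_equal(round(100 * proportion(649082, 4426342)$proportion, 1), 14.7)
  expect_equal(round(100 * proportion(246406, 649082)$proportion, 1), 38.0)
  expect_equal(round(100 * proportion(4426342, 82170094)$proportion, 1), 5.4)
})

test_that("Wilson interval brackets the estimate and survives 0/n and n/n", {
  for (kn in list(c(0, 100), c(100, 100), c(5, 10), c(1, 1000))) {
    p <- proportion(kn[1], kn[2])
    expect_true(p$ci95[1] <= p$proportion && p$proportion <= p$ci95[2])
    expect_false(any(is.nan(p$ci95)))
    expect_true(p$ci95[1] >= 0 && p$ci95[2] <= 1)
  }
  expect_equal(proportion(0, 100)$ci95[1], 0)
  expect_error(proportion(1, 0), "denominator")
  expect_error(proportion(5, 4), "numerator")
})

test_that("deaths per 1,000 inpatients matches printed rates and is additive", {
  expect_equal(round(deaths_per_1000(833815, 82170094), 2), 10.15)
  expect_equal(round(deaths_per_1000(212591, 82170094), 2), 2.59)
  expect_equal(round(deaths_per_1000(621224, 82170094), 2), 7.56)
  expect_equal(deaths_per_1000(0, 1000), 0)
  ## numerators partitioning deaths over a shared denominator add exactly
  expect_equal(deaths_per_1000(212591, 82170094) +
                 deaths_per_1000(621224, 82170094),
               deaths_per_1000(833815, 82170094))
  expect_error(deaths_per_1000(1, 0), "positive")
})

test_that("LOS summary uses interpolated quartiles and recombines across strata", {
  s <- los_summary(38)
  expect_equal(s$median, 38); expect_equal(s$q1, 38); expect_equal(s$q3, 38)
  s <- los_summary(c(10, 20, 30, 40))
  expect_equal(s$median, 25)
  expect_equal(s$q1, 17.5)
  expect_equal(s$q3, 32.5)
  ## stratified means recombine to the overall mean
  v <- c(3, 7, 11, 20, 40)
  surv <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  s <- los_summary(v, surv)
  overall <- s[s$stratum == "overall"]
  parts <- s[s$stratum != "overall"]
  expect_equal(overall$mean,
               sum(parts$mean * parts$n) / sum(parts$n))
  expect_error(los_summary(numeric(0)), "empty")
})

test_that("Cochran-Armitage: null, two-sample equivalence, and affine invariance", {
  ## equal proportions every year -> Z = 0, p = 1
  r <- cochran_armitage(2010:2014, rep(30, 5), rep(100, 5))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, "flat")
  ## 2-year series equals the pooled two-sample proportion z-test
  e <- c(20, 35); n <- c(100, 110)
  z_ca <- abs(cochran_armitage(1:2, e, n)$statistic)
  p1 <- e[1] / n[1]; p2 <- e[2] / n[2]; pp <- sum(e) / sum(n)
  z_two <- abs(p1 - p2) / sqrt(pp * (1 - pp) * (1 / n[1] + 1 / n[2]))
  expect_equal(z_ca, z_two, tolerance = 1e-12)
  ## affine rescaling of scores leaves Z unchanged
  z1 <- cochran_armitage(2010:2016, c(5, 8, 9, 13, 14, 18, 21),
                         rep(50, 7))$statistic
  z2 <- cochran_armitage(10 * (2010:2016) + 3, c(5, 8, 9, 13, 14, 18, 21),
                         rep(50, 7))$statistic
  expect_equal(z1, z2, tolerance = 1e-12)
  ## matches the built-in trend chi-square (independent implementation)
  pt <- suppressWarnings(stats::prop.trend.test(c(5, 8, 9, 13, 14, 18, 21),
                                                rep(50, 7)))
  expect_equal(z1^2, unname(pt$statistic), tolerance = 1e-10)
  expect_error(cochran_armitage(1:3, c(0, 0, 0), rep(10, 3)), "degenerate")
})

test_that("Cochran-Armitage p approximates the exact conditional permutation p", {
  ## 3 years, 10 admissions each; exact null = multivariate hypergeometric
  ## given the total event count
  years <- 1:3; totals <- rep(10, 3); events <- c(1, 3, 6)
  obs <- abs(cochran_armitage(years, events, totals)$statistic)
  tot <- sum(events)
  p_exact <- 0
  for (e1 in 0:10) for (e2 in 0:10) {
    e3 <- tot - e1 - e2
    if (e3 < 0 || e3 > 10) next
    pr <- choose(10, e1) * choose(10, e2) * choose(10, e3) /
      choose(30, tot)
    z <- abs(cochran_armitage(years, c(e1, e2, e3), totals)$statistic)
    if (z >= obs - 1e-12) p_exact <- p_exact + pr
  }
  p_norm <- cochran_armitage(years, events, totals)$p_value
  expect_lt(abs(p_norm - p_exact), 0.02)
})

test_that("linear trend recovers exact lines and hand-computed OLS", {
  r <- linear_trend(2010:2014, 5 + 2 * (2010:2014))
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  r <- linear_trend(2010:2014, rep(7, 5))
  expect_equal(r$slope, 0)
  expect_equal(r$r_squared, 0)
  expect_equal(r$direction, "flat")
  ## 5-point series vs normal equations
  x <- 2010:2014; y <- c(3.1, 4.0, 3.7, 5.2, 5.9)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r <- linear_trend(x, y)
  expect_equal(r$slope, slope_hand, tolerance = 1e-12)
  pred <- mean(y) + slope_hand * (x - mean(x))
  r2_hand <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(r$r_squared, r2_hand, tolerance = 1e-12)
  expect_error(linear_trend(rep(2010, 3), 1:3), "singular")
})

test_that("group comparisons: identity, hand-computed chi-square, separation", {
  set.seed(1)
  x <- rnorm(50)
  r <- compare_groups("mean", x, x)
  expect_gt(r$p_value, 0.99)
  ## 2x2 chi-square (10/100 vs 30/100) against Sum (O-E)^2/E
  tab <- rbind(c(10, 90), c(30, 70))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi_hand <- sum((tab - E)^2 / E)
  r <- compare_groups("categorical", c(10, 100), c(30, 100))
  expect_equal(r$statistic, chi_hand, tolerance = 1e-12)
  ## complete separation gives U = 0
  r <- compare_groups("rank", c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_warning(compare_groups("categorical", c(0, 2), c(1, 2)),
                 "expected cell")
})
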