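test_that("identical seeds give byte-identical tables; different seeds differ", {
  cfg <- sim_config(n_admissions_per_year = 150, years = 2012:2014, seed = 11)
  a <- simulate_claims(cfg)
  b <- simulate_claims(cfg)
  expect_identical(a$admissions, b$admissions)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_claims(sim_config(n_admissions_per_year = 150,
                                   years = 2012:2014, seed = 12))
  expect_false(identical(a$admissions, c_$admissions))
})

test_that("generated claims satisfy the schema invariants", {
  sim <- simulate_claims(sim_config(n_admissions_per_year = 400,
                                    years = 2010:2012, seed = 3))
  expect_silent(validate_claims(sim$admissions, sim$diagnoses, sim$events))
  ## non-survivors die on their last hospital day
  dd <- sim$admissions[sim$admissions$died_in_hospital == TRUE]
  expect_true(all(dd$death_day == dd$los_days))
  ## truth hierarchy
  expect_true(all(!sim$truth$is_shock | sim$truth$is_sepsis))
  expect_true(all(!sim$truth$is_community_onset | sim$truth$is_sepsis))
})

test_that("empirical prevalences converge to configured probabilities", {
  n <- 110000
  cfg <- sim_config(n_admissions_per_year = 10000, seed = 21,
                    sepsis_logit_drift = 0)
  sim <- simulate_claims(cfg, events = FALSE)
  p_hat <- mean(sim$truth$is_sepsis)
  se <- sqrt(0.054 * (1 - 0.054) / n)
  expect_lt(abs(p_hat - 0.054), 3 * se)
  p_shock <- mean(sim$truth$is_shock[sim$truth$is_sepsis])
  n_sep <- sum(sim$truth$is_sepsis)
  expect_lt(abs(p_shock - 0.147), 3 * sqrt(0.147 * 0.853 / n_sep))
})

test_that("shock mortality exceeds non-shock mortality when the shock log-OR is positive", {
  sim <- simulate_claims(sim_config(n_admissions_per_year = 10000, seed = 8),
                         events = FALSE)
  d <- merge(sim$admissions, sim$truth, by = "admission_id")
  m_shock <- mean(d$died_in_hospital[d$is_shock])
  m_nonshock <- mean(d$died_in_hospital[d$is_sepsis & !d$is_shock])
  expect_gt(m_shock, m_nonshock)
  ## magnitudes near the configured surveillance targets
  expect_lt(abs(m_shock - 0.365), 0.08)
  expect_lt(abs(m_nonshock - 0.20), 0.05)
})

test_that("the fixture catalog covers its documented cases and rejects unknowns", {
  expect_error(make_fixture("nope"), "unknown fixture")
  fx <- make_fixture("worked_example_16")
  expect_equal(nrow(fx$admissions), 16L)
  expect_equal(nrow(fx$expected), 16L)
  de <- make_fixture("death_exception")
  expect_true(de$expected$is_sepsis)
  an <- make_fixture("all_negative")
  expect_false(any(an$expected$is_sepsis))
})
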