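test_that("saturated 2x2 fit reproduces the ad/bc odds ratio exactly", {
  ## exposed: 30 events / 70 non-events; unexposed: 10 / 90
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  x <- c(rep(TRUE, 100), rep(FALSE, 100))
  fit <- logistic_fit(y, data.frame(exposed = x))
  or <- fit$coefficients$or[fit$coefficients$term == "exposed"]
  expect_equal(or, (30 * 90) / (70 * 10), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("intercept-only model gives the logit of the overall rate", {
  y <- c(rep(1, 37), rep(0, 63))
  fit <- logistic_fit(y, data.frame())
  expect_equal(fit$coefficients$estimate, stats::qlogis(0.37),
               tolerance = 1e-8)
  expect_equal(nrow(fit$coefficients), 1L)
})

test_that("IRLS matches glm estimates and Wald SEs on simulated data", {
  set.seed(42)
  n <- 3000
  x1 <- rnorm(n); x2 <- runif(n) < 0.4; g <- sample(c("a", "b", "c"), n,
                                                    replace = TRUE)
  eta <- -1 + 0.5 * x1 + 0.8 * x2 + 0.3 * (g == "b")
  y <- runif(n) < plogis(eta)
  fit <- logistic_fit(y, data.frame(x1 = x1, x2 = x2, g = g))
  gl <- stats::glm(y ~ x1 + x2 + g, family = binomial,
                   data = data.frame(x1, x2, g))
  expect_equal(sort(fit$coefficients$estimate), sort(unname(coef(gl))),
               tolerance = 1e-6)
  se_glm <- sort(unname(summary(gl)$coefficients[, "Std. Error"]))
  expect_equal(sort(fit$coefficients$se), se_glm, tolerance = 1e-5)
})

test_that("log-likelihood is non-decreasing across IRLS iterations", {
  set.seed(9)
  n <- 500
  x <- rnorm(n)
  y <- runif(n) < plogis(-2 + 3 * x)
  fit <- logistic_fit(y, data.frame(x = x))
  expect_true(all(diff(fit$loglik) >= -1e-9))
})

test_that("degenerate inputs raise the documented errors", {
  y <- rep(c(0, 1), 25)
  expect_error(logistic_fit(y, data.frame(k = rep(1, 50))), "constant")
  expect_error(logistic_fit(c(0, 1, 2), data.frame(x = 1:3)), "binary")
  ## complete separation on a gap
  ys <- c(rep(0, 25), rep(1, 25))
  xs <- c(seq(-5, -1, length.out = 25), seq(1, 5, length.out = 25))
  expect_error(logistic_fit(ys, data.frame(x = xs)), "separation")
  ## missing covariates are dropped as complete cases
  yy <- rep(c(0, 1), 30)
  xx <- rnorm(60); xx[1:5] <- NA
  fit <- logistic_fit(yy, data.frame(x = xx))
  expect_equal(fit$n_dropped, 5L)
  expect_equal(fit$n, 55L)
})

test_that("a known per-year odds ratio is recovered from ground-truth refits", {
  res <- recover_year_or(true_or = 0.96, n_admissions = 200000, n_reps = 3,
                         seed = 400)
  expect_true(all(res$or_estimates > 0.90 & res$or_estimates < 1.02))
})
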