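test_that("logistic MLE matches an independent likelihood-maximisation oracle", {
  x <- matrix(c(-2, -1, 0, 0, 1, 2), ncol = 1)
  y <- c(0, 1, 0, 1, 0, 1)  # overlapping outcomes keep the MLE finite
  f <- fit_logistic_mle(x, y = y)
  o <- oracle_logistic(x, y)
  expect_lt(max(abs(c(f$intercept, f$coefficients) - o$coef)), 1e-6)
  expect_lt(abs(f$loglik_model - o$loglik), 1e-8)

  # a larger random fixture, cross-checked against stats::glm as well
  set.seed(21)
  x2 <- matrix(rnorm(300 * 4), ncol = 4)
  y2 <- rbinom(300, 1, plogis(0.3 + drop(x2 %*% c(0.6, -0.4, 0, 0.2))))
  f2 <- fit_logistic_mle(x2, y = y2)
  o2 <- oracle_logistic(x2, y2)
  g2 <- glm.fit(cbind(1, x2), y2, family = binomial(),
                control = list(epsilon = 1e-14))
  expect_lt(max(abs(c(f2$intercept, f2$coefficients) - o2$coef)), 1e-6)
  expect_lt(max(abs(c(f2$intercept, f2$coefficients) - g2$coefficients)),
            1e-6)
  expect_true(f2$converged)
})

test_that("null log-likelihood has its closed form and LR is non-negative", {
  set.seed(31)
  x <- matrix(rnorm(400), ncol = 2)
  y <- rbinom(200, 1, 0.3)
  f <- fit_logistic_mle(x, y = y)
  pbar <- mean(y)
  expect_equal(f$loglik_null,
               200 * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar)))
  expect_gte(f$lr, 0)
  expect_gte(f$loglik_model, f$loglik_null - 1e-8)
  expect_error(fit_logistic_mle(x, y = rep(0, 200)), "constant")
})

test_that("fitted coefficients are consistent at the null", {
  set.seed(41)
  x <- matrix(rnorm(2e4 * 3), ncol = 3)
  y <- rbinom(2e4, 1, 0.4)
  f <- fit_logistic_mle(x, y = y)
  # SE of each slope is about 1/sqrt(n * p(1-p)) for standardised predictors
  se <- 1 / sqrt(2e4 * 0.24)
  expect_true(all(abs(f$coefficients) < 3 * se))
})

test_that("Cox-Snell R2 follows its formula and limits", {
  expect_equal(cox_snell_r2(0, 50), 0)
  expect_equal(cox_snell_r2(10, 100), 1 - exp(-0.1))
  r <- cox_snell_r2(c(1, 10, 100, 1000), 100)
  expect_true(all(diff(r) > 0))
  expect_lt(r[4], 1)
  expect_error(cox_snell_r2(-1, 100), "non-negative")
})

test_that("LR statistic is invariant to affine predictor rescaling", {
  set.seed(51)
  x <- matrix(rnorm(500 * 3), ncol = 3)
  y <- rbinom(500, 1, plogis(drop(x %*% c(0.4, -0.2, 0.1))))
  f1 <- fit_logistic_mle(x, y = y)
  x2 <- sweep(sweep(x, 2, c(2, 0.5, 10), "*"), 2, c(1, -3, 0.2), "+")
  f2 <- fit_logistic_mle(x2, y = y)
  expect_lt(abs(f1$lr - f2$lr), 1e-6)
})

test_that("C-statistic equals exhaustive pair counting and handles ties", {
  expect_equal(c_statistic(c(0.1, 0.6, 0.4, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(c_statistic(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  p <- c(0.1, 0.2, 0.3, 0.8, 0.9)
  expect_equal(c_statistic(p, c(0, 0, 0, 1, 1)), 1)
  set.seed(61)
  for (i in 1:5) {
    ph <- round(runif(30), 1)  # rounded so ties occur
    yy <- rbinom(30, 1, 0.4)
    if (all(yy == 0) || all(yy == 1)) next
    expect_equal(c_statistic(ph, yy), oracle_cstat(ph, yy))
  }
  expect_error(c_statistic(runif(5), rep(1, 5)), "non-event")
})

test_that("complementary scores reverse the C-statistic on tie-free data", {
  set.seed(71)
  ph <- runif(50)
  yy <- rbinom(50, 1, 0.5)
  expect_equal(c_statistic(ph, yy) + c_statistic(-ph, yy), 1)
})

test_that("calibration slope recovers known distortions of the truth", {
  set.seed(81)
  n <- 1e6
  eta <- rnorm(n, 0, 1.2)
  y <- rbinom(n, 1, plogis(eta))
  # perfectly calibrated predictions: slope 1
  cal <- calibration_slope(plogis(eta), y)
  expect_lt(abs(cal$slope - 1), 0.01)
  # doubled linear predictor: slope exactly halves
  cal2 <- calibration_slope(plogis(2 * eta), y)
  expect_lt(abs(cal2$slope - 0.5), 0.01)
  expect_error(calibration_slope(rep(0.4, 10), rbinom(10, 1, 0.5)),
               "constant")
})

test_that("calibration slope matches a brute-force two-parameter oracle", {
  set.seed(91)
  p_hat <- plogis(rnorm(8, 0, 1.5))
  y <- c(1, 0, 0, 1, 1, 0, 1, 0)
  cal <- calibration_slope(p_hat, y)
  o <- oracle_logistic(matrix(qlogis(p_hat), ncol = 1), y)
  expect_lt(abs(cal$slope - o$coef[2]), 1e-6)
  expect_lt(abs(cal$intercept - o$coef[1]), 1e-6)
})

test_that("apparent calibration slope of a model on its own data is exactly 1", {
  set.seed(95)
  x <- matrix(rnorm(300 * 2), ncol = 2)
  y <- rbinom(300, 1, plogis(0.5 + drop(x %*% c(0.7, -0.5))))
  f <- fit_logistic_mle(x, y = y)
  cal <- calibration_slope(predict(f, x), y)
  # forced by the maximum-likelihood score equations
  expect_lt(abs(cal$slope - 1), 1e-6)
  expect_lt(abs(cal$intercept), 1e-6)
})
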