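test_that("random scenarios satisfy their structural invariants", {
  cfg <- scenario_config()
  for (k in 1:25) {
    sc <- sample_scenario(cfg, seed = derive_seed(101, k))
    expect_true(sc$q_meas >= 1 && sc$q_meas <= 30)
    expect_true(sc$q_unmeas >= 1 && sc$q_unmeas <= 30)
    expect_true(all(abs(sc$beta) < 0.5))
    expect_true(sc$n_dev >= 100 && sc$n_dev <= 5000)
    expect_equal(sc$beta0, qlogis(sc$prop))
    expect_equal(sc$omega, t(sc$omega))
    ev <- eigen(sc$omega, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_equal(diag(sc$omega), rep(1, nrow(sc$omega)))
  }
})

test_that("the same seed reproduces the same scenario and dataset", {
  a <- sample_scenario(seed = 7)
  b <- sample_scenario(seed = 7)
  expect_identical(a, b)
  d1 <- generate_dataset(a, 200, seed = 3)
  d2 <- generate_dataset(a, 200, seed = 3)
  expect_identical(d1, d2)
})

test_that("random PSD correlation matrices are valid and non-degenerate", {
  expect_equal(random_psd_correlation(1), matrix(1, 1, 1))
  expect_error(random_psd_correlation(0), "at least 1")
  r <- random_psd_correlation(5, seed = 42)
  expect_equal(r, t(r))
  expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  off <- r[upper.tri(r)]
  expect_gt(max(abs(off)), 0.01)  # dependence actually induced
})

test_that("generated data follow the multivariate-normal logistic mechanism", {
  # null coefficients: prevalence equals the target proportion exactly
  sc <- toy_scenario(q_meas = 3L, beta = c(0, 0, 0), prop = 0.5)
  sc$omega <- diag(3)
  d <- generate_dataset(sc, 1e5, seed = 1)
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(mean(d$y) - 0.5), 3 * se)
  expect_true(all(d$true_p == 0.5))

  # outcome rate tracks the true probabilities
  sc2 <- sample_scenario(seed = 99)
  d2 <- generate_dataset(sc2, 1e5, seed = 2)
  se2 <- sqrt(mean(d2$true_p * (1 - d2$true_p)) / 1e5)
  expect_lt(abs(mean(d2$y) - mean(d2$true_p)), 3 * se2)
  expect_true(all(d2$true_p > 0 & d2$true_p < 1))
  expect_true(all(d2$y %in% c(0L, 1L)))

  # realized prevalence stays near the target even with nonzero effects
  expect_lt(abs(mean(d2$y) - sc2$prop), 0.1)
})

test_that("empirical covariance of generated predictors matches omega", {
  sc <- sample_scenario(scenario_config(covariance_mode = "identity"),
                        seed = 11)
  d <- generate_dataset(sc, 1e5, seed = 4)
  cc <- cor(d$x)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02)

  sc2 <- sample_scenario(scenario_config(covariance_mode = "random_psd"),
                         seed = 12)
  d2 <- generate_dataset(sc2, 1e5, seed = 5)
  expect_lt(max(abs(cov(d2$x) - sc2$omega)), 0.05)
})

test_that("coefficient rescaling hits a target C-statistic", {
  b <- rescale_coefficients_to_c(c(0.3, -0.2), 0.3, 0.75, seed = 8)
  expect_gt(attr(b, "k"), 0)
  # independent re-simulation on a fresh cohort with sampled outcomes
  set.seed(4242)
  x <- matrix(rnorm(4e5 * 2), ncol = 2)
  eta <- drop(x %*% as.numeric(b))
  b0 <- uniroot(function(b0) mean(plogis(b0 + eta)) - 0.3, c(-30, 30))$root
  y <- rbinom(4e5, 1, plogis(b0 + eta))
  expect_lt(abs(c_statistic(plogis(b0 + eta), y) - 0.75), 0.005)

  # monotone: a higher target needs a larger multiplier
  b2 <- rescale_coefficients_to_c(c(0.3, -0.2), 0.3, 0.85, seed = 8)
  expect_gt(attr(b2, "k"), attr(b, "k"))
  expect_error(rescale_coefficients_to_c(c(0, 0), 0.3, 0.75), "zero vector")
})

test_that("alternative mechanism decouples predictor count from the C-statistic", {
  cfg <- scenario_config(dgm = "independent_c",
                         rescale = rescale_settings(sim_n = 1e4))
  qs <- integer(0); cs <- numeric(0)
  for (k in 1:200) {
    sc <- sample_scenario_alt(cfg, seed = derive_seed(500, k))
    expect_identical(sc$q_unmeas, 0L)
    expect_true(sc$target_c > 0.55 && sc$target_c < 0.95)
    # population C of the true model on a fresh cohort
    d <- generate_dataset(sc, 1e4, seed = derive_seed(500, k, 3))
    qs <- c(qs, sc$q_meas)
    cs <- c(cs, c_statistic(d$true_p, d$y))
  }
  expect_lt(abs(cor(qs, cs)), 0.15)
})

test_that("scenarios round-trip through JSON", {
  sc <- sample_scenario(seed = 77)
  js <- scenario_to_json(sc)
  back <- scenario_from_json(js)
  expect_equal(back$beta, sc$beta)
  expect_equal(back$omega, sc$omega, tolerance = 1e-12)
  expect_identical(back$n_dev, sc$n_dev)
  expect_identical(back$covariance_mode, sc$covariance_mode)
  path <- tempfile(fileext = ".json")
  scenario_to_json(sc, path)
  expect_equal(scenario_from_json(path)$beta, sc$beta)
})
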