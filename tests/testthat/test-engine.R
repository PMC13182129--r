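test_that("the Monte-Carlo standard deviation uses divisor n", {
  expect_equal(scenario_sd(rep(3, 10)), 0)
  expect_equal(scenario_sd(c(0, 2)), 1)  # divisor n, not n - 1
  set.seed(161)
  v <- rnorm(250)
  expect_equal(scenario_sd(v), sqrt(sum((v - mean(v))^2) / 250),
               tolerance = 1e-12)
})

test_that("a near-asymptotic scenario shows negligible bias", {
  sc <- toy_scenario(q_meas = 2L, n_dev = 5000L, beta = c(0.5, -0.4),
                     prop = 0.3)
  r <- run_study1_scenario(sc, iterations = 20, validation_n = 5e5,
                           b_boot = 60, seed = 1001)
  expect_lt(abs(r$bias_vh), 0.03)
  expect_lt(abs(r$bias_boot), 0.03)
  expect_gt(r$mean_sopt, 0.95)
  expect_lte(r$mean_sopt, 1.02)
  expect_equal(nrow(r$records), 20)
  expect_equal(r$epp, mean(r$records$events) / 2)
})

test_that("a single iteration gives zero sd and MCE", {
  sc <- toy_scenario(n_dev = 400L)
  r <- run_study1_scenario(sc, iterations = 1, validation_n = 2e4,
                           b_boot = 30, seed = 5)
  expect_equal(r$sd_vh, 0)
  expect_equal(r$mce_vh, 0)
  expect_equal(r$bias_vh, r$records$s_vh[1] - r$records$s_opt[1])
})

test_that("scenario runs are deterministic under a fixed seed", {
  sc <- toy_scenario(n_dev = 300L)
  r1 <- run_study1_scenario(sc, iterations = 4, validation_n = 2e4,
                            b_boot = 25, seed = 42)
  r2 <- run_study1_scenario(sc, iterations = 4, validation_n = 2e4,
                            b_boot = 25, seed = 42)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$bias_vh, r2$bias_vh)

  r3 <- run_study2_scenario(sc, iterations = 3, validation_n = 2e4,
                            seed = 43,
                            nsim_settings = samplesize_sim_settings(
                              m_reps = 40L, m_reps_final = 80L,
                              validation_n = 5e3, tolerance = 0.02,
                              max_evals = 12L, sigma_sim_n = 2e4))
  r4 <- run_study2_scenario(sc, iterations = 3, validation_n = 2e4,
                            seed = 43,
                            nsim_settings = samplesize_sim_settings(
                              m_reps = 40L, m_reps_final = 80L,
                              validation_n = 5e3, tolerance = 0.02,
                              max_evals = 12L, sigma_sim_n = 2e4))
  expect_identical(r3$records, r4$records)
  expect_identical(r3$n_sim, r4$n_sim)
})

test_that("bias definitions follow the per-iteration deviations", {
  sc <- toy_scenario(n_dev = 500L)
  r <- run_study1_scenario(sc, iterations = 6, validation_n = 2e4,
                           b_boot = 30, seed = 77)
  used <- r$records$fit_converged & !is.na(r$records$s_boot)
  expect_equal(r$bias_vh,
               mean(r$records$s_vh[used] - r$records$s_opt[used]))
  expect_equal(r$mce_boot,
               scenario_sd(r$records$s_boot[used] - r$records$s_opt[used]) /
                 sqrt(sum(used)))
})

test_that("study-1 exclusion rules partition scenarios with reasons", {
  base <- data.frame(scenario_id = 1:5, mean_svh = c(0.8, -0.1, 0.7, 0.6, 0.9),
                     mean_sboot = c(0.9, 0.5, 2.5, 0.8, 0.85),
                     mean_r2app = c(0.1, 0.2, 0.3, -0.05, 0.2),
                     boot_fail_rate = c(0, 0, 0, 0, 0.2))
  out <- apply_exclusions_study1(base)
  expect_equal(nrow(out$kept) + nrow(out$excluded), 5)
  expect_equal(out$kept$scenario_id, 1L)
  expect_equal(out$excluded$exclusion_reason[out$excluded$scenario_id == 2],
               "mean_s_vh<0")
  expect_equal(out$excluded$exclusion_reason[out$excluded$scenario_id == 3],
               "mean_s_boot>2")
  expect_equal(out$excluded$exclusion_reason[out$excluded$scenario_id == 5],
               "bootstrap_failures")
})

test_that("study-2 exclusions route non-convergent searches separately", {
  base <- data.frame(scenario_id = 1:4,
                     n_original = c(500L, 600L, 700L, 800L),
                     nsim_converged = c(TRUE, FALSE, TRUE, TRUE),
                     mean_sopt_original = c(0.9, 1.1, -0.1, 0.88),
                     mean_sopt_sim = c(0.9, NA, NA, 2.5))
  out <- apply_exclusions_study2(base)
  expect_equal(out$kept$scenario_id, 1L)
  expect_equal(out$not_converged$scenario_id, 2L)  # reported, not dropped
  expect_setequal(out$excluded$scenario_id, c(3L, 4L))
  expect_equal(nrow(out$kept) + nrow(out$not_converged) +
                 nrow(out$excluded), 4)
})

test_that("stratified summaries match a sort-and-interpolate oracle", {
  set.seed(171)
  df <- data.frame(c_pop = runif(40, 0.55, 0.9), bias_vh = rnorm(40, 0, 0.1))
  tab <- summarize_results(df, "bias_vh")
  all_row <- tab[tab$stratum == "All", ]
  expect_equal(all_row$n_scenarios, 40)
  for (p in c(0.025, 0.25, 0.5, 0.75, 0.975)) {
    cn <- paste0("p", gsub("\\.", "_", format(100 * p, trim = TRUE)))
    expect_equal(all_row[[cn]], oracle_quantile(df$bias_vh, p))
  }
  # percentiles are nondecreasing in every stratum
  qcols <- grep("^p", names(tab), value = TRUE)
  for (i in seq_len(nrow(tab))) {
    qs <- as.numeric(tab[i, qcols])
    if (all(!is.na(qs))) expect_true(all(diff(qs) >= 0))
  }
  # magnitude summaries dominate raw means (triangle inequality)
  mag <- summarize_results(df, "magnitude_bias_vh")
  expect_gte(mag$mean[1], abs(all_row$mean))

  # single scenario in a stratum: all percentiles equal that value
  one <- data.frame(c_pop = 0.62, bias_vh = 0.05)
  t1 <- summarize_results(one, "bias_vh")
  r <- t1[t1$stratum == "0.60<=C_pop<0.65", ]
  expect_true(all(as.numeric(r[qcols]) == 0.05))
  # empty strata are reported with zero count, not an error
  expect_equal(t1[t1$stratum == "0.70<=C_pop<0.75", ]$n_scenarios, 0)
})

test_that("within a small-sample scenario the optimal shrinkage is more
           variable than its bootstrap estimate", {
  sc <- toy_scenario(q_meas = 2L, n_dev = 150L, beta = c(0.6, -0.5),
                     prop = 0.3)
  r <- run_study1_scenario(sc, iterations = 40, validation_n = 3e4,
                           b_boot = 60, seed = 2024)
  used <- r$records$fit_converged
  expect_gt(scenario_sd(r$records$s_opt[used]),
            scenario_sd(r$records$s_boot[used]))
})
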