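test_that("simulated cohorts always pass validation and derivation", {
  for (s in c(2, 19, 73)) {
    raw <- simulate_cohort(sim_config(n = 200L), seed = s)
    cohort <- validate_cohort(raw)
    expect_equal(nrow(cohort$data), 200)
    expect_equal(nrow(cohort$rejected), 0)
    d <- prepare_cohort(cohort)
    expect_true(all(d$time_months > 0))
    expect_true(all(d$event %in% 0:1))
    expect_true(all(d$ldl_c <= d$tc & d$hdl_c < d$tc))
  }
})

test_that("simulation is deterministic given a seed", {
  a <- simulate_cohort(sim_config(n = 150L), seed = 8)
  b <- simulate_cohort(sim_config(n = 150L), seed = 8)
  expect_identical(a, b)
  expect_error(simulate_cohort(sim_config()), "seed")
})

test_that("empirical lipid medians match the configured log-normal medians", {
  cfg <- sim_config(n = 50000L)
  d <- simulate_cohort(cfg, seed = 55)
  target <- exp(cfg$lipid_log_mean)
  got <- c(median(d$tc), median(d$tg), median(d$hdl_c), median(d$ldl_c))
  expect_equal(unname(got), unname(target), tolerance = 0.02)
})

test_that("zero administrative follow-up produces zero events", {
  cfg <- sim_config(n = 100L, admin_censor_months = 0)
  d <- simulate_cohort(cfg, seed = 4)
  expect_equal(sum(d$event_occurred), 0)
})

test_that("event proportion rises monotonically with baseline hazard and
           effects separate risk groups", {
  props <- sapply(c(600, 245, 100), function(scale) {
    cfg <- sim_config(n = 4000L, weibull_scale = scale)
    mean(simulate_cohort(cfg, seed = 60)$event_occurred)
  })
  expect_true(all(diff(props) > 0))

  # the baseline is anchored to the cohort-average relative hazard, so a
  # covariate effect redistributes risk rather than inflating the marginal
  # rate: with a positive hypertension effect, events concentrate in the
  # exposed and the gap widens with the effect size
  gaps <- sapply(c(0, 1, 2), function(b) {
    cfg <- sim_config(n = 8000L, log_hr = c(hypertension = b))
    d <- simulate_cohort(cfg, seed = 61)
    mean(d$event_occurred[d$hypertension]) -
      mean(d$event_occurred[!d$hypertension])
  })
  expect_lt(abs(gaps[1]), 0.03)
  expect_true(all(diff(gaps) > 0))
})

test_that("the null-copy column replicates the LDL-C marginal independently", {
  cfg <- sim_config(n = 20000L, null_copy_parameter = TRUE)
  d <- simulate_analysis_cohort(cfg, seed = 66)
  expect_true("ldl_copy" %in% names(d))
  expect_equal(median(d$ldl_copy), exp(cfg$lipid_log_mean[["ldl"]]),
               tolerance = 0.03)
  expect_lt(abs(cor(d$ldl_copy, d$ldl_c)), 0.03)
})

test_that("standardization constants and truth are emitted with the cohort", {
  d <- simulate_cohort(sim_config(n = 50L), seed = 9)
  truth <- attr(d, "truth")
  expect_equal(truth$seed, 9)
  expect_true(all(c("ldl", "age", "gensini") %in%
                    names(truth$standardization)))
  expect_equal(truth$weibull_scale, sim_config()$weibull_scale)
})

test_that("recover_parameters is reproducible and structured", {
  cfg <- sim_config(n = 300L)
  r1 <- recover_parameters(cfg, n_reps = 10L, parameters = "ldl_c",
                           seed = 77, truth_n = 3000)
  r2 <- recover_parameters(cfg, n_reps = 10L, parameters = "ldl_c",
                           seed = 77, truth_n = 3000)
  expect_identical(r1, r2)
  s <- r1$summary$ldl_c
  expect_true(is.finite(s$truth_beta))
  expect_true(s$convergence_rate > 0.5)
  expect_error(recover_parameters(cfg, n_reps = 5L, seed = 1), "n_reps")
})

test_that("config validation rejects broken inputs", {
  expect_error(sim_config(nonsense = 1), "unknown sim_config")
  bad_corr <- matrix(c(1, 2, 2, 1), 2, 2)   # eigenvalues 3 and -1
  expect_error(sim_config(lipid_corr = bad_corr), "positive-definite")
  expect_error(sim_config(weibull_shape = -1))
})
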