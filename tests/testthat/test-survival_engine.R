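test_that("tertile cutpoints follow the linear-interpolation quantile rule", {
  t6 <- assign_tertiles(1:6)
  # brute-force h = (n-1)p + 1 on the sorted values
  expect_equal(unname(t6$cutpoints["q33"]), oracle_percentile(1:6, 1 / 3))
  expect_equal(unname(t6$cutpoints["q67"]), oracle_percentile(1:6, 2 / 3))
  expect_equal(as.vector(table(t6$labels)), c(2, 2, 2))

  t9 <- assign_tertiles(1:9)
  expect_equal(unname(t9$cutpoints),
               c(oracle_percentile(1:9, 1 / 3), oracle_percentile(1:9, 2 / 3)))
  expect_equal(as.vector(table(t9$labels)), c(3, 3, 3))

  # ties at a cutpoint fall to the lower tertile
  v <- c(1, 2, 2, 3, 4, 10)
  tt <- assign_tertiles(v)
  expect_true(all(tt$labels[v <= tt$cutpoints["q33"]] == "T1"))

  expect_error(assign_tertiles(rep(5, 10)), "degenerate")
  expect_error(assign_tertiles(c(1, 2, NA)), "NA")
})

test_that("the 4-subject worked example matches the written likelihood", {
  time <- c(1, 2, 3, 4)
  status <- c(1, 1, 1, 1)
  x <- matrix(c(1, 0, 1, 0), ncol = 1, dimnames = list(NULL, "x"))

  fit0 <- fit_cox(x, time, status, iter_max = 0L)
  expect_equal(fit0$loglik_null, log(1 / 24), tolerance = 1e-12)

  # the partial likelihood written out by hand for this dataset
  f <- function(b) log(exp(b) / (2 * exp(b) + 2)) + log(1 / (exp(b) + 2)) +
    log(exp(b) / (exp(b) + 1))
  b_star <- oracle_golden_max(f)
  fit <- fit_cox(x, time, status)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), b_star, tolerance = 1e-6)
  expect_equal(fit$loglik, f(b_star), tolerance = 1e-9)
})

test_that("fit_cox matches golden-section maximization of the Efron
           partial likelihood on small tied datasets", {
  for (ds in oracle_test_datasets()) {
    if (length(unique(ds$x)) < 2 || sum(ds$status) < 1) next
    f <- function(b) oracle_efron_loglik(b, ds$time, ds$status, ds$x)
    b_star <- oracle_golden_max(f)
    fit <- fit_cox(matrix(ds$x, ncol = 1), ds$time, ds$status)
    if (!fit$converged) next   # monotone-likelihood sets have no maximizer
    expect_equal(unname(fit$beta), b_star, tolerance = 1e-4)
    expect_equal(fit$loglik, f(b_star), tolerance = 1e-8)
  }
})

test_that("monotone likelihood is flagged, not silently reported", {
  fit <- fit_cox(matrix(c(1, 0), ncol = 1), c(1, 2), c(1, 1))
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "monotone|singular|step-halving")
  expect_error(hr_top_vs_bottom(
    structure(fit, class = "cox_fit")), "converge")
})

test_that("degenerate designs raise errors naming the problem", {
  x <- cbind(a = c(1, 1, 1, 1), b = c(1, 0, 1, 0))
  expect_error(fit_cox(x, 1:4, c(1, 1, 0, 0)), "constant covariate.*a")
  expect_error(fit_cox(x[, 2, drop = FALSE], 1:4, c(0, 0, 0, 0)),
               "at least one event")
})

test_that("Cox estimates depend on time ranks only", {
  d <- small_cohort(seed = 11, n = 200)
  des <- build_tertile_design(d, "ldl_c")
  fit1 <- fit_cox(des$x, des$time, des$event)
  fit2 <- fit_cox(des$x, exp(des$time / 20), des$event)  # strictly increasing
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-10)
})

test_that("rescaling a covariate rescales its coefficient inversely", {
  d <- small_cohort(seed = 12, n = 200)
  des <- build_tertile_design(d, "ldl_c")
  fit1 <- fit_cox(des$x, des$time, des$event)
  x2 <- des$x
  x2[, "age"] <- 10 * x2[, "age"]
  fit2 <- fit_cox(x2, des$time, des$event)
  expect_equal(unname(fit2$beta["age"]), unname(fit1$beta["age"]) / 10,
               tolerance = 1e-7)
  expect_equal(unname(fit2$beta["d3"]), unname(fit1$beta["d3"]),
               tolerance = 1e-7)
})

test_that("beta and se agree with the survival package on synthetic cohorts", {
  for (s in 1:5) {
    d <- small_cohort(seed = 100 + s, n = 300)
    des <- build_tertile_design(d, "ldl_c")
    fit <- fit_cox(des$x, des$time, des$event)
    ref <- survival::coxph(survival::Surv(des$time, des$event) ~ des$x,
                           ties = "efron")
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
  }
})

test_that("top-vs-bottom HR applies the Wald formulas", {
  d <- small_cohort(seed = 13, n = 250)
  fit <- fit_tertile_cox(d, "ldl_c")
  top <- hr_top_vs_bottom(fit)
  b <- unname(fit$beta["d3"]); se <- unname(fit$se["d3"])
  expect_equal(top$hr, exp(b))
  expect_equal(top$ci_lo, exp(b - 1.959964 * se))
  expect_equal(top$ci_hi, exp(b + 1.959964 * se))
  expect_equal(top$p, 2 * pnorm(-abs(b / se)))
  expect_true(top$ci_lo <= top$hr && top$hr <= top$ci_hi)

  # direct-arithmetic spot check at published-scale numbers
  b0 <- 0.9746; se0 <- 0.3829
  expect_equal(exp(b0), 2.650107, tolerance = 1e-6)
  expect_equal(exp(b0 - 1.959964 * se0), 1.251233, tolerance = 1e-6)
  expect_equal(exp(b0 + 1.959964 * se0), 5.612915, tolerance = 1e-6)
})
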