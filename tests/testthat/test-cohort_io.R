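test_that("a well-formed cohort file loads with one record per row", {
  path <- write_tiny_cohort_csv()
  cohort <- load_cohort(path)
  expect_s3_class(cohort, "cohort")
  expect_equal(nrow(cohort$data), 3)
  expect_equal(nrow(cohort$rejected), 0)
  # BMI derived from weight/height where absent
  expect_equal(cohort$data$bmi[1], 72 / 1.70^2)
  expect_equal(cohort$data$bmi[2], 24.0)
})

test_that("missing mandatory columns raise a schema error naming them", {
  path <- write_tiny_cohort_csv()
  d <- read.csv(path)
  d$hdl_c <- NULL
  path2 <- tempfile(fileext = ".csv")
  write.csv(d, path2, row.names = FALSE)
  expect_error(load_cohort(path2), "hdl_c")
})

test_that("rows violating record invariants are rejected with reasons", {
  path <- write_tiny_cohort_csv()
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$event_date[1] <- ""           # event without a date
  d$age[2] <- -4                  # impossible age
  d$last_contact_date[3] <- "2016-01-01"  # before discharge
  cohort <- validate_cohort(d)
  expect_equal(nrow(cohort$data), 0)
  expect_equal(cohort$rejected$row, 1:3)
  expect_match(cohort$rejected$reason[1], "no event_date")
  expect_match(cohort$rejected$reason[2], "age")
  expect_match(cohort$rejected$reason[3], "last_contact_date before")
})

test_that("unparseable dates are reported as row-level errors", {
  path <- write_tiny_cohort_csv()
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$discharge_date[2] <- "10/05/2016"
  cohort <- validate_cohort(d)
  expect_equal(nrow(cohort$rejected), 1)
  expect_match(cohort$rejected$reason, "unparseable date in discharge_date")
})

test_that("cohort CSV round-trips bit-for-bit through write and load", {
  path <- write_tiny_cohort_csv()
  cohort <- load_cohort(path)
  path2 <- tempfile(fileext = ".csv")
  write_cohort(cohort, path2)
  cohort2 <- load_cohort(path2)
  expect_identical(cohort$data, cohort2$data)
  expect_true(file.exists(paste0(path2, ".validation.json")))
})

test_that("schema remapping finds renamed columns", {
  path <- write_tiny_cohort_csv()
  d <- read.csv(path, stringsAsFactors = FALSE)
  names(d)[names(d) == "ldl_c"] <- "LDL"
  cohort <- validate_cohort(d, cohort_schema(ldl_c = "LDL"))
  expect_equal(nrow(cohort$data), 3)
  expect_error(cohort_schema(not_a_field = "x"), "unknown schema field")
})

test_that("derive_bmi follows weight / height^2 and rejects bad input", {
  expect_equal(derive_bmi(72, 1.70), 72 / 2.89)
  expect_equal(derive_bmi(23.7, 1.0), 23.7)  # height 1 m identity
  expect_error(derive_bmi(70, 0), "height")
  expect_error(derive_bmi(-1, 1.7), "weight")
})

test_that("CKD-EPI eGFR matches the piecewise equation", {
  # both piecewise terms at 1 and age factor -> 1 in the age -> 0 limit
  expect_equal(ckd_epi_egfr(79.56, 1e-9, "male"), 141, tolerance = 1e-6)
  # frozen value from arbitrary-precision evaluation of the equation
  # (male, age 65, creatinine 72.6 umol/L)
  expect_equal(ckd_epi_egfr(72.6, 65, "male"), 92.73867060276166,
               tolerance = 1e-12)
  # at Scr = kappa and equal age the sex terms cancel except the 1.018
  expect_equal(ckd_epi_egfr(0.7 * 88.4, 50, "female") /
                 ckd_epi_egfr(0.9 * 88.4, 50, "male"), 1.018)
  expect_error(ckd_epi_egfr(-1, 60, "male"), "creatinine")
  expect_error(ckd_epi_egfr(80, 0, "male"), "age")
})

test_that("eGFR is strictly decreasing in creatinine and in age", {
  cr <- seq(40, 200, by = 5)
  for (s in c("male", "female")) {
    e <- ckd_epi_egfr(cr, 60, s)
    expect_true(all(diff(e) < 0))
    ages <- seq(20, 90, by = 2)
    e2 <- ckd_epi_egfr(80, ages, s)
    expect_true(all(diff(e2) < 0))
  }
})

test_that("CKD flag is a strict < 60 threshold", {
  expect_true(ckd_flag(59.9))
  expect_false(ckd_flag(60.0))
  expect_false(ckd_flag(89.9))   # a typical cohort median is not CKD
  expect_error(ckd_flag(-1), "egfr")
})

test_that("time-to-event uses days / 30.4375 from discharge", {
  path <- write_tiny_cohort_csv()
  cohort <- load_cohort(path)
  d <- derive_time_to_event(cohort)
  # patient A1: discharge 2016-03-01, MI 2017-06-15 -> 471 days
  expect_equal(d$time_months[1], 471 / 30.4375)
  expect_equal(d$event[1], 1L)
  expect_equal(d$event[2], 0L)
  expect_true(all(d$time_months > 0))
})

test_that("same-day endpoints are rejected at derivation", {
  path <- write_tiny_cohort_csv()
  raw <- read.csv(path, stringsAsFactors = FALSE)
  raw$event_date[1] <- raw$discharge_date[1]
  raw$last_contact_date[1] <- raw$discharge_date[1]
  cohort <- validate_cohort(raw)
  expect_equal(nrow(cohort$data), 3)   # dates are consistent, so valid
  d <- derive_time_to_event(cohort)
  expect_equal(nrow(d), 2)
  rej <- attr(d, "rejected")
  expect_match(rej$reason, "non-positive follow-up")
})
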