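# Independent oracles used to check the package's own implementations.
# These deliberately share no code with the package: the partial likelihood
# is written out naively, quantiles are computed from the textbook formula,
# and maximization is a bisection-free golden-section search.

# Efron-corrected Cox log partial likelihood for a single covariate,
# evaluated by direct enumeration over unique event times.
oracle_efron_loglik <- function(beta, time, status, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    s_r <- sum(exp(eta[R]))
    s_d <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(s_r - (l / d) * s_d)
    }
  }
  ll
}

# golden-section maximization of a unimodal function on [lo, hi]
oracle_golden_max <- function(f, lo = -20, hi = 20, tol = 1e-9) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - phi * (b - a)
  d <- a + phi * (b - a)
  fc <- f(c); fd <- f(d)
  while (b - a > tol) {
    if (fc > fd) {
      b <- d; d <- c; fd <- fc
      c <- b - phi * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + phi * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}

# textbook linear-interpolation percentile: h = (n-1)p + 1 on sorted values
oracle_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  k <- floor(h)
  if (k >= n) return(x[n])
  x[k] + (h - k) * (x[k + 1] - x[k])
}

# small deterministic survival datasets (1 covariate, with ties) for
# oracle-equivalence sweeps
oracle_test_datasets <- function() {
  sets <- list(
    list(time = c(1, 2, 3, 4), status = c(1, 1, 1, 1), x = c(1, 0, 1, 0)),
    list(time = c(1, 1, 2, 3), status = c(1, 1, 1, 0), x = c(1, 0, 1, 0)),
    list(time = c(2, 2, 2, 5, 6), status = c(1, 1, 0, 1, 0),
         x = c(0.5, -1, 2, 0, 1)),
    list(time = c(1, 1, 1, 2, 2, 3), status = c(1, 0, 1, 1, 1, 0),
         x = c(1, 1, 0, 0, 1, 0)),
    list(time = c(3, 1, 4, 1, 5, 9, 2, 6), status = c(1, 1, 0, 1, 1, 0, 1, 1),
         x = c(0.2, 1.5, -0.3, 0.8, -1.2, 0.1, 2.0, -0.5))
  )
  set.seed(421)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    sets[[length(sets) + 1]] <- list(
      time = sample(1:5, n, replace = TRUE),     # guarantees ties
      status = pmin(rbinom(n, 1, 0.7) + c(1, rep(0, n - 1)), 1),
      x = round(rnorm(n), 2)
    )
  }
  sets
}

# compact synthetic analysis cohort for unit tests (fast, moderate size)
small_cohort <- function(seed, n = 250L, ...) {
  simulate_analysis_cohort(sim_config(n = as.integer(n), ...), seed = seed)
}

# write a minimal valid 3-row cohort CSV; returns the path
write_tiny_cohort_csv <- function(path = tempfile(fileext = ".csv")) {
  d <- data.frame(
    patient_id = c("A1", "A2", "A3"),
    age = c(64, 71, 58), sex = c("male", "female", "male"),
    weight = c(72, 60, 80), height = c(1.70, 1.58, 1.75),
    bmi = c(NA, 24.0, NA),
    diabetes = c(TRUE, FALSE, FALSE), hypertension = c(TRUE, TRUE, FALSE),
    prior_stent = c(FALSE, FALSE, TRUE), triple_vessel = c(FALSE, TRUE, FALSE),
    gensini = c(37, 52, 18), creatinine = c(72.6, 61.3, 86.8),
    tc = c(5.1, 4.5, 5.7), tg = c(1.8, 1.3, 2.7),
    hdl_c = c(1.1, 1.3, 0.9), ldl_c = c(3.2, 2.7, 3.7),
    lpa = c(196, 84, 472.5), apob = c(1.0, 0.8, 1.2),
    apoa1 = c(1.3, 1.4, 1.1),
    discharge_date = c("2016-03-01", "2016-05-10", "2017-01-20"),
    event_occurred = c(TRUE, FALSE, FALSE),
    event_type = c("mi", "none", "none"),
    event_date = c("2017-06-15", "", ""),
    last_contact_date = c("2017-06-15", "2020-05-30", "2020-05-30"),
    stringsAsFactors = FALSE
  )
  write.csv(d, path, row.names = FALSE, na = "")
  path
}
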