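#' Tertile exposure coding
#'
#' Splits a numeric exposure at its empirical 1/3 and 2/3 quantiles
#' (linear-interpolation definition, `quantile(type = 7)`). Values at or
#' below the lower cutpoint are labelled T1, values above the lower and at
#' or below the upper cutpoint T2, and the rest T3 — so ties at a cutpoint
#' fall to the lower tertile.
#'
#' @param values numeric vector, no NAs; at least 3 distinct values.
#' @return List with `cutpoints` (named `q33`, `q67`), `labels` (factor
#'   with levels T1 < T2 < T3) and the dummy columns `d2`, `d3` coding
#'   T2 vs T1 and T3 vs T1.
#' @export
assign_tertiles <- function(values) {
  if (anyNA(values)) stop("values must not contain NA")
  if (length(unique(values)) < 3) {
    stop("degenerate exposure: fewer than 3 distinct values")
  }
  q <- unname(quantile(values, c(1 / 3, 2 / 3), type = 7))
  labels <- cut(values, breaks = c(-Inf, q[1], q[2], Inf),
                labels = c("T1", "T2", "T3"), right = TRUE)
  list(cutpoints = c(q33 = q[1], q67 = q[2]),
       labels = labels,
       d2 = as.numeric(labels == "T2"),
       d3 = as.numeric(labels == "T3"))
}

# default adjustment set: the model covariates entered alongside the
# tertile dummies
adjustment_covariates <- function() {
  c("age", "sex01", "bmi", "diabetes", "hypertension", "gensini")
}

#' Build the adjusted tertile design for one lipid parameter
#'
#' Restricts to complete cases for the parameter, the adjusters and the
#' follow-up fields (complete-case policy is per model, so missingness in
#' one parameter does not shrink another parameter's model), codes
#' tertiles, and assembles the design matrix `[d2, d3, adjusters]`.
#'
#' @param data analysis-ready data frame from [prepare_cohort()] or
#'   [simulate_cohort()].
#' @param parameter column name of the lipid parameter.
#' @param covariates adjustment covariate columns.
#' @return List (`tertile_design`): `parameter`, `cutpoints`, `labels`,
#'   `x` (design matrix), `time`, `event`, `n`, `n_events`.
#' @export
build_tertile_design <- function(data, parameter,
                                 covariates = adjustment_covariates()) {
  cols <- c(parameter, covariates, "time_months", "event")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  d <- data[cols]
  for (j in seq_along(d)) d[[j]] <- as.numeric(d[[j]])
  keep <- complete.cases(d)
  d <- d[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("fewer than 3 complete cases for ", parameter)

  tert <- assign_tertiles(d[[parameter]])
  x <- cbind(d2 = tert$d2, d3 = tert$d3,
             as.matrix(d[, covariates, drop = FALSE]))
  structure(
    list(parameter = parameter, cutpoints = tert$cutpoints,
         labels = tert$labels, x = x,
         time = d$time_months, event = as.integer(d$event),
         n = nrow(d), n_events = sum(d$event)),
    class = "tertile_design"
  )
}

#' Fit a Cox proportional-hazards model (Efron ties)
#'
#' Maximizes the Cox log partial likelihood with Efron's correction for
#' tied event times by Newton-Raphson with step-halving, starting from
#' beta = 0. Convergence requires both a log-likelihood change below
#' `eps_loglik` and a gradient max-norm below `eps_grad`. The
#' variance-covariance matrix is the inverse observed information at the
#' optimum. A coefficient walking past `beta_max` in absolute value is
#' treated as a monotone-likelihood diagnosis and the fit is flagged
#' non-converged rather than erroring.
#'
#' @param x numeric design matrix (n x p), columns named.
#' @param time follow-up times (any positive scale; only ranks and ties
#'   matter).
#' @param event 0/1 event indicator.
#' @param iter_max maximum Newton iterations.
#' @param eps_loglik,eps_grad convergence tolerances.
#' @param beta_max divergence bound on |beta|.
#' @return Object of class `cox_fit`: `beta`, `cov`, `se`, `hr`, `ci_lo`,
#'   `ci_hi`, `p`, `loglik`, `loglik_null`, `converged`, `diagnostic`,
#'   `iter`, `n`, `n_events`.
#' @export
fit_cox <- function(x, time, event, iter_max = 100L, eps_loglik = 1e-9,
                    eps_grad = 1e-6, beta_max = 50) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  event <- as.integer(event)
  stopifnot(length(time) == n, length(event) == n,
            all(event %in% c(0L, 1L)), all(is.finite(time)))
  if (anyNA(x)) stop("design matrix contains NA; apply complete cases first")
  if (sum(event) < 1) stop("at least one event is required")
  const <- apply(x, 2, function(col) max(col) == min(col))
  if (any(const)) {
    stop("constant covariate(s): ",
         paste(colnames(x)[const], collapse = ", "))
  }

  ord <- order(time, decreasing = TRUE)
  xs <- x[ord, , drop = FALSE]
  ts <- as.double(time[ord])
  ss <- event[ord]

  p <- ncol(x)
  beta <- rep(0, p)
  st <- cox_efron_stats(xs, ts, ss, beta)
  loglik_null <- st$loglik
  ll <- st$loglik
  converged <- FALSE
  diagnostic <- ""
  iter <- 0L

  for (iter in seq_len(iter_max)) {
    delta <- tryCatch(solve(st$information, st$gradient),
                      error = function(e) NULL)
    if (is.null(delta)) {
      diagnostic <- "singular information matrix"
      break
    }
    # a true optimum needs both a flat gradient and a vanishing Newton
    # increment; a monotone likelihood keeps |delta| large even where the
    # gradient is numerically tiny
    if (max(abs(st$gradient)) < eps_grad && max(abs(delta)) < 1e-4) {
      converged <- TRUE
      break
    }
    # accept a step that does not decrease the log likelihood beyond
    # floating-point resolution at its magnitude
    ll_tol <- max(abs(ll), 1) * 1e-12
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      st_new <- cox_efron_stats(xs, ts, ss, beta_new)
      if (is.finite(st_new$loglik) && st_new$loglik >= ll - ll_tol) break
      step <- step / 2
      if (step < 2^-20) break
    }
    if (step < 2^-20) {
      diagnostic <- "step-halving exhausted without likelihood increase"
      break
    }
    improvement <- st_new$loglik - ll
    beta <- beta_new
    st <- st_new
    ll <- st$loglik
    if (max(abs(beta)) > beta_max) {
      diagnostic <- "monotone likelihood suspected: |beta| exceeded bound"
      break
    }
    if (abs(improvement) < eps_loglik && max(abs(st$gradient)) < eps_grad &&
        max(abs(step * delta)) < 1e-4) {
      converged <- TRUE
      break
    }
  }
  if (!converged && diagnostic == "") {
    diagnostic <- "iteration limit reached"
  }

  cov <- tryCatch(solve(st$information), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(cov), 0))
  z <- beta / se
  names(beta) <- colnames(x)
  dimnames(cov) <- list(colnames(x), colnames(x))

  structure(
    list(beta = beta, cov = cov, se = setNames(se, colnames(x)),
         hr = exp(beta),
         ci_lo = exp(beta - Z_95 * se), ci_hi = exp(beta + Z_95 * se),
         p = setNames(2 * pnorm(-abs(z)), colnames(x)),
         loglik = ll, loglik_null = loglik_null,
         converged = converged, diagnostic = diagnostic, iter = iter,
         n = n, n_events = sum(event)),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox proportional hazards fit (Efron ties): n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  if (!x$converged) cat("NOT CONVERGED: ", x$diagnostic, "\n", sep = "")
  tab <- data.frame(beta = x$beta, se = x$se, HR = x$hr,
                    lower95 = x$ci_lo, upper95 = x$ci_hi, p = x$p)
  print(round(tab, digits))
  cat("log partial likelihood:", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Fit the adjusted tertile Cox model for one lipid parameter
#'
#' Convenience wrapper: builds the tertile design with
#' [build_tertile_design()] and fits it with [fit_cox()].
#'
#' @inheritParams build_tertile_design
#' @param ... passed to [fit_cox()].
#' @return A `cox_fit` with attribute `design` (the `tertile_design`).
#' @export
fit_tertile_cox <- function(data, parameter,
                            covariates = adjustment_covariates(), ...) {
  design <- build_tertile_design(data, parameter, covariates)
  fit <- fit_cox(design$x, design$time, design$event, ...)
  attr(fit, "design") <- design
  fit
}

#' Highest- vs lowest-tertile hazard ratio
#'
#' Extracts the T3-vs-T1 hazard ratio (`exp(beta_d3)`) with its Wald 95%
#' interval and p-value from an adjusted tertile fit. Non-convergence is
#' propagated as an error.
#'
#' @param fit a converged `cox_fit` whose design contains a `d3` column.
#' @return List: `hr`, `ci_lo`, `ci_hi`, `p`.
#' @export
hr_top_vs_bottom <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) {
    stop("Cox fit did not converge: ", fit$diagnostic)
  }
  if (!"d3" %in% names(fit$beta)) stop("fit has no tertile dummy d3")
  list(hr = unname(fit$hr["d3"]), ci_lo = unname(fit$ci_lo["d3"]),
       ci_hi = unname(fit$ci_hi["d3"]), p = unname(fit$p["d3"]))
}
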