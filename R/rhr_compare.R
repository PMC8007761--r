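#' Ratio of hazard ratios
#'
#' The headline comparison statistic: the top-vs-bottom tertile hazard
#' ratio of a lipid parameter divided by that of the referent (LDL-C),
#' both from adjusted Cox models fitted on the same cohort.
#'
#' @param hr_param hazard ratio of the comparison parameter.
#' @param hr_referent hazard ratio of the referent parameter.
#' @return `hr_param / hr_referent`.
#' @export
rhr_point <- function(hr_param, hr_referent) {
  if (any(!is.finite(hr_param) | hr_param <= 0)) {
    stop("hr_param must be > 0")
  }
  if (any(!is.finite(hr_referent) | hr_referent <= 0)) {
    stop("hr_referent must be > 0")
  }
  hr_param / hr_referent
}

#' Percentile confidence interval
#'
#' Empirical percentile limits at `100 * alpha/2` and `100 * (1 - alpha/2)`
#' under the linear-interpolation quantile definition (`type = 7`).
#'
#' @param samples numeric vector of at least 2 finite values.
#' @param alpha two-sided error rate (0.05 gives the 2.5th and 97.5th
#'   percentiles).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
percentile_ci <- function(samples, alpha = 0.05) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2) stop("need at least 2 finite samples")
  q <- unname(quantile(samples, c(alpha / 2, 1 - alpha / 2), type = 7))
  c(lo = q[1], hi = q[2])
}

#' Paired percentile-bootstrap confidence interval for the RHR
#'
#' Draws `B` bootstrap resamples of the cohort (patients with
#' replacement). Within each resample the tertile cutpoints of both the
#' comparison parameter and the referent are re-derived (the tertile
#' construction is part of the estimator, so its sampling variability
#' belongs in the interval; set `recut_tertiles = FALSE` to freeze the
#' original cutpoints instead), both adjusted Cox models are fitted on
#' the same resample (paired), and the bootstrap statistic is the ratio
#' of their T3-vs-T1 hazard ratios. The interval is the 2.5th/97.5th
#' percentile of the retained bootstrap ratios; the point estimate comes
#' from the original cohort. Resamples with a degenerate exposure or a
#' non-converged fit are discarded and redrawn, up to `10 * B` extra
#' draws; if more than 20% of all draws are discarded the call fails
#' with diagnostics.
#'
#' @param data analysis-ready data frame ([prepare_cohort()] or
#'   [simulate_cohort()]).
#' @param parameter comparison lipid parameter column.
#' @param referent referent column (default `"ldl_c"`).
#' @param B number of bootstrap resamples (the study-default is 5000).
#' @param seed mandatory RNG seed; one seed governs the whole bootstrap.
#' @param covariates adjustment covariates.
#' @param recut_tertiles re-derive tertile cutpoints inside each resample
#'   (default) or reuse the full-cohort cutpoints.
#' @param alpha two-sided error rate for the percentile interval.
#' @return Object of class `rhr_result`: `parameter`, `referent`,
#'   `rhr` (point), `ci_lo`, `ci_hi`, `n_boot`, `n_discarded`, `seed`,
#'   `hr_param`, `hr_referent`, and the retained bootstrap draws in
#'   `boot_rhr`.
#' @export
bootstrap_rhr <- function(data, parameter, referent = "ldl_c", B = 5000L,
                          seed, covariates = adjustment_covariates(),
                          recut_tertiles = TRUE, alpha = 0.05) {
  if (missing(seed)) stop("seed is mandatory for bootstrap_rhr")
  B <- as.integer(B)
  if (B < 2) stop("B must be >= 2")

  fit_param <- fit_tertile_cox(data, parameter, covariates)
  fit_ref <- fit_tertile_cox(data, referent, covariates)
  hr_param <- hr_top_vs_bottom(fit_param)$hr
  hr_ref <- hr_top_vs_bottom(fit_ref)$hr
  point <- rhr_point(hr_param, hr_ref)

  cols <- unique(c(parameter, referent, covariates, "time_months", "event"))
  d <- data[, cols, drop = FALSE]
  for (j in seq_along(d)) d[[j]] <- as.numeric(d[[j]])
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)

  frozen <- NULL
  if (!recut_tertiles) {
    frozen <- list(
      param = assign_tertiles(d[[parameter]])$cutpoints,
      ref = assign_tertiles(d[[referent]])$cutpoints
    )
  }

  one_hr <- function(dd, col, frozen_cut) {
    if (is.null(frozen_cut)) {
      tert <- assign_tertiles(dd[[col]])
      d2 <- tert$d2
      d3 <- tert$d3
    } else {
      lab <- cut(dd[[col]], c(-Inf, frozen_cut[1], frozen_cut[2], Inf),
                 labels = c("T1", "T2", "T3"), right = TRUE)
      d2 <- as.numeric(lab == "T2")
      d3 <- as.numeric(lab == "T3")
    }
    x <- cbind(d2 = d2, d3 = d3,
               as.matrix(dd[, covariates, drop = FALSE]))
    fit <- fit_cox(x, dd$time_months, dd$event)
    if (!fit$converged) stop("non-converged resample fit")
    unname(exp(fit$beta["d3"]))
  }

  set.seed(seed)
  max_draws <- B + 10L * B
  rhrs <- numeric(0)
  draws <- 0L
  discarded <- 0L
  while (length(rhrs) < B && draws < max_draws) {
    draws <- draws + 1L
    idx <- sample.int(n, n, replace = TRUE)
    dd <- d[idx, , drop = FALSE]
    r <- tryCatch({
      hp <- one_hr(dd, parameter, frozen$param)
      hf <- if (identical(parameter, referent)) hp
            else one_hr(dd, referent, frozen$ref)
      hp / hf
    }, error = function(e) NA_real_)
    if (is.finite(r) && r > 0) rhrs <- c(rhrs, r) else discarded <- discarded + 1L
  }
  if (length(rhrs) < B) {
    stop("bootstrap_rhr: redraw cap reached with only ", length(rhrs),
         " of ", B, " usable resamples (", discarded, " discarded)")
  }
  if (discarded > 0.2 * draws) {
    stop("bootstrap_rhr: ", discarded, " of ", draws,
         " resamples discarded (> 20%); cohort too unstable for the ",
         "paired bootstrap")
  }

  ci <- percentile_ci(rhrs, alpha)
  structure(
    list(parameter = parameter, referent = referent,
         rhr = point, ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"]),
         n_boot = B, n_discarded = discarded, seed = seed,
         hr_param = hr_param, hr_referent = hr_ref,
         recut_tertiles = recut_tertiles, boot_rhr = rhrs),
    class = "rhr_result"
  )
}

#' @export
print.rhr_result <- function(x, digits = 3, ...) {
  cat("RHR ", x$parameter, " vs ", x$referent, ": ",
      round(x$rhr, digits), " (95% CI ", round(x$ci_lo, digits), " to ",
      round(x$ci_hi, digits), "); B = ", x$n_boot, ", discarded = ",
      x$n_discarded, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
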