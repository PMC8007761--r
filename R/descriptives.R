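#' Summary and test selection for one baseline variable
#'
#' Implements the Table-1 decision rule. Categorical variables are
#' summarised as counts (percent) and compared by a chi-square test
#' without continuity correction (with an automatic Fisher exact fallback
#' when any expected cell count is below 5). Continuous variables are
#' checked for normality in each group with a Kolmogorov-Smirnov test
#' against a normal distribution with moment-estimated parameters (set
#' `ks_variant = "lilliefors"` for the Lilliefors-corrected variant);
#' when both groups look normal (p >= 0.05) the summary is mean +/- SD
#' with a Welch t-test, otherwise median (IQR) with a Mann-Whitney U
#' test. A group with fewer than 3 continuous observations makes the
#' normality check undecidable and falls back to Mann-Whitney with a
#' warning.
#'
#' @param values variable values (numeric, logical, or factor/character
#'   for categorical).
#' @param group two-level grouping vector (e.g. MACE yes/no).
#' @param kind `"auto"` detects binary/categorical vs continuous;
#'   override with `"continuous"` or `"categorical"`.
#' @param ks_variant `"ks"` (one-sample KS, moment-estimated normal) or
#'   `"lilliefors"` (requires the nortest package).
#' @param variable label carried into the output row.
#' @return One-row data frame: `variable`, `summary_all`,
#'   `summary_group1`, `summary_group2`, `test_used`, `p_value`.
#' @export
choose_summary_and_test <- function(values, group,
                                    kind = c("auto", "continuous",
                                             "categorical"),
                                    ks_variant = c("ks", "lilliefors"),
                                    variable = deparse(substitute(values))) {
  kind <- match.arg(kind)
  ks_variant <- match.arg(ks_variant)
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- group[keep]
  glev <- unique(group)
  if (length(glev) != 2) stop("group must have exactly 2 levels")
  g1 <- values[group == glev[1]]
  g2 <- values[group == glev[2]]
  if (!length(g1) || !length(g2)) stop("each group must be non-empty")

  if (kind == "auto") {
    categorical <- is.logical(values) || is.factor(values) ||
      is.character(values) || length(unique(values)) <= 2
    kind <- if (categorical) "categorical" else "continuous"
  }

  if (kind == "categorical") {
    tab <- table(factor(values), factor(group, levels = glev))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      test_used <- "fisher"
      p <- fisher.test(tab)$p.value
    } else {
      test_used <- "chi_square"
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    pos <- if (is.logical(values)) "TRUE" else rownames(tab)[nrow(tab)]
    pct <- function(v) {
      k <- sum(as.character(v) == pos)
      sprintf("%d (%.1f%%)", k, 100 * k / length(v))
    }
    row <- data.frame(
      variable = variable, summary_all = pct(values),
      summary_group1 = pct(g1), summary_group2 = pct(g2),
      test_used = test_used, p_value = p, stringsAsFactors = FALSE
    )
    return(row)
  }

  values <- as.numeric(values)
  g1 <- as.numeric(g1)
  g2 <- as.numeric(g2)
  normal <- NA
  if (length(g1) < 3 || length(g2) < 3) {
    warning("group with < 3 observations: normality undecidable, ",
            "falling back to Mann-Whitney")
    normal <- FALSE
  } else {
    pnorms <- vapply(list(g1, g2), function(g) {
      if (sd(g) == 0) return(0)  # point mass is maximally non-normal
      if (ks_variant == "lilliefors") {
        nortest::lillie.test(g)$p.value
      } else {
        suppressWarnings(
          ks.test(g, "pnorm", mean(g), sd(g))$p.value
        )
      }
    }, numeric(1))
    normal <- all(pnorms >= 0.05)
  }

  if (normal) {
    test_used <- "t"
    p <- t.test(g1, g2)$p.value   # Welch, unequal variance
    fmt <- function(g) sprintf("%.2f ± %.2f", mean(g), sd(g))
  } else {
    test_used <- "mann_whitney"
    p <- suppressWarnings(wilcox.test(g1, g2)$p.value)
    fmt <- function(g) {
      q <- quantile(g, c(0.25, 0.5, 0.75), type = 7)
      sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3])
    }
  }
  data.frame(
    variable = variable, summary_all = fmt(values),
    summary_group1 = fmt(g1), summary_group2 = fmt(g2),
    test_used = test_used, p_value = p, stringsAsFactors = FALSE
  )
}

#' Table-1 style baseline comparison
#'
#' Builds the descriptive table comparing baseline characteristics between
#' patients with and without MACE (or any other two-level grouping),
#' selecting summary format and hypothesis test per variable via
#' [choose_summary_and_test()].
#'
#' @param data analysis-ready data frame.
#' @param variables character vector of columns to summarise.
#' @param group_var two-level grouping column (default `"event"`).
#' @param ks_variant passed to [choose_summary_and_test()].
#' @return Data frame with one row per variable.
#' @export
table_one <- function(data, variables, group_var = "event",
                      ks_variant = c("ks", "lilliefors")) {
  ks_variant <- match.arg(ks_variant)
  rows <- lapply(variables, function(v) {
    choose_summary_and_test(data[[v]], data[[group_var]],
                            ks_variant = ks_variant, variable = v)
  })
  do.call(rbind, rows)
}
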