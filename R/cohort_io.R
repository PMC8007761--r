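#' Default cohort column schema
#'
#' Maps the internal field names used throughout the package to the column
#' names expected in a cohort CSV. Override entries to adapt to a differently
#' named file, e.g. `cohort_schema(ldl_c = "LDL")`.
#'
#' Units are fixed: lipids in mmol/L, creatinine in umol/L, apolipoproteins
#' in g/L, lipoprotein(a) in mg/dL, weight in kg, height in m. Dates are
#' ISO-8601 (YYYY-MM-DD).
#'
#' @param ... named overrides, `internal_name = "csv_column_name"`.
#' @return Named character vector mapping internal names to CSV columns.
#' @export
cohort_schema <- function(...) {
  schema <- c(
    patient_id = "patient_id", age = "age", sex = "sex",
    weight = "weight", height = "height", bmi = "bmi",
    diabetes = "diabetes", hypertension = "hypertension",
    prior_stent = "prior_stent", triple_vessel = "triple_vessel",
    gensini = "gensini", creatinine = "creatinine",
    tc = "tc", tg = "tg", hdl_c = "hdl_c", ldl_c = "ldl_c",
    lpa = "lpa", apob = "apob", apoa1 = "apoa1",
    discharge_date = "discharge_date", event_occurred = "event_occurred",
    event_type = "event_type", event_date = "event_date",
    last_contact_date = "last_contact_date"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(schema))
    if (length(bad)) stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    schema[names(overrides)] <- overrides
  }
  schema
}

# Fields that must be present as columns. bmi is conditionally mandatory:
# each row needs either bmi or both weight and height.
.mandatory_fields <- c(
  "patient_id", "age", "sex", "diabetes", "hypertension", "gensini",
  "creatinine", "tc", "tg", "hdl_c", "ldl_c", "discharge_date",
  "event_occurred", "event_type", "event_date", "last_contact_date"
)

.event_types <- c("cv_death", "stroke", "mi", "revascularization", "none")

.parse_date <- function(x) {
  if (inherits(x, "Date")) {
    return(list(date = x, bad = rep(FALSE, length(x))))
  }
  out <- as.Date(rep(NA, length(x)))
  x <- as.character(x)
  ok <- !is.na(x) & x != ""
  if (any(ok)) {
    out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  }
  list(date = out, bad = ok & is.na(out))
}

.parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Load and validate a cohort CSV
#'
#' Reads a patient-level cohort table, checks mandatory columns, validates
#' every row against the record invariants (positive age and BMI,
#' non-negative Gensini score, event dates consistent with the discharge
#' date, parseable ISO dates) and returns the validated records together
#' with a rejection report. BMI is computed from weight and height where not
#' supplied directly.
#'
#' @param path path to a CSV file with a header row.
#' @param schema column-name map from [cohort_schema()].
#' @return An object of class `cohort`: a list with `data` (validated
#'   records, one row per patient, internal column names), `rejected`
#'   (data frame of row numbers, patient ids and reasons) and `n_read`.
#' @export
load_cohort <- function(path, schema = cohort_schema()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(raw, schema)
}

#' Validate an in-memory cohort table
#'
#' Same contract as [load_cohort()] but starting from a data frame whose
#' columns follow `schema`.
#'
#' @inheritParams load_cohort
#' @param raw data frame as read from the cohort CSV.
#' @return An object of class `cohort`; see [load_cohort()].
#' @export
validate_cohort <- function(raw, schema = cohort_schema()) {
  missing_cols <- setdiff(unname(schema[.mandatory_fields]), names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  # rename to internal names; absent optional columns become NA
  d <- data.frame(row = seq_len(nrow(raw)))
  for (f in names(schema)) {
    col <- schema[[f]]
    d[[f]] <- if (col %in% names(raw)) raw[[col]] else NA
  }

  n <- nrow(d)
  reasons <- vector("list", n)
  add_reason <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }

  num_fields <- c("age", "weight", "height", "bmi", "gensini", "creatinine",
                  "tc", "tg", "hdl_c", "ldl_c", "lpa", "apob", "apoa1")
  for (f in num_fields) d[[f]] <- suppressWarnings(as.numeric(d[[f]]))
  for (f in c("diabetes", "hypertension", "prior_stent", "triple_vessel",
              "event_occurred")) {
    d[[f]] <- .parse_logical(d[[f]])
  }
  d$sex <- tolower(trimws(as.character(d$sex)))
  d$event_type <- tolower(trimws(as.character(d$event_type)))
  d$event_type[is.na(d$event_type) | d$event_type == ""] <- "none"

  for (f in c("discharge_date", "event_date", "last_contact_date")) {
    p <- .parse_date(d[[f]])
    add_reason(p$bad, paste0("unparseable date in ", f))
    d[[f]] <- p$date
  }

  # derive bmi where absent but weight/height present
  need_bmi <- is.na(d$bmi) & !is.na(d$weight) & !is.na(d$height) &
    d$weight > 0 & d$height > 0
  d$bmi[need_bmi] <- d$weight[need_bmi] / d$height[need_bmi]^2

  add_reason(is.na(d$age) | d$age <= 0, "age must be > 0")
  add_reason(!d$sex %in% c("male", "female"), "sex must be male or female")
  add_reason(is.na(d$bmi) | d$bmi <= 0,
             "bmi missing and not derivable from weight/height")
  add_reason(is.na(d$gensini) | d$gensini < 0, "gensini must be >= 0")
  add_reason(is.na(d$creatinine) | d$creatinine <= 0, "creatinine must be > 0")
  for (f in c("tc", "tg", "hdl_c", "ldl_c")) {
    add_reason(is.na(d[[f]]) | d[[f]] <= 0, paste0(f, " must be > 0"))
  }
  add_reason(is.na(d$event_occurred), "event_occurred must be true/false")
  add_reason(!d$event_type %in% .event_types, "unknown event_type")
  add_reason(is.na(d$discharge_date), "discharge_date missing")
  add_reason(is.na(d$last_contact_date), "last_contact_date missing")

  ev <- !is.na(d$event_occurred) & d$event_occurred
  add_reason(ev & is.na(d$event_date), "event_occurred but no event_date")
  add_reason(ev & d$event_type == "none",
             "event_occurred but event_type is none")
  add_reason(ev & !is.na(d$event_date) & !is.na(d$discharge_date) &
               d$event_date < d$discharge_date,
             "event_date before discharge_date")
  add_reason(!is.na(d$last_contact_date) & !is.na(d$discharge_date) &
               d$last_contact_date < d$discharge_date,
             "last_contact_date before discharge_date")

  bad <- vapply(reasons, function(r) length(r) > 0, logical(1))
  rejected <- data.frame(
    row = d$row[bad],
    patient_id = as.character(d$patient_id[bad]),
    reason = vapply(reasons[bad], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE
  )

  out <- list(data = d[!bad, setdiff(names(d), "row"), drop = FALSE],
              rejected = rejected, n_read = n)
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort: ", nrow(x$data), " validated records (",
      nrow(x$rejected), " rejected of ", x$n_read, " read)\n", sep = "")
  invisible(x)
}

#' Body mass index
#'
#' @param weight body weight in kg.
#' @param height height in m.
#' @return BMI in kg/m^2, `weight / height^2`.
#' @export
derive_bmi <- function(weight, height) {
  if (any(!is.finite(weight) | weight <= 0)) stop("weight must be > 0")
  if (any(!is.finite(height) | height <= 0)) stop("height must be > 0")
  weight / height^2
}

#' CKD-EPI (2009) estimated glomerular filtration rate
#'
#' The creatinine-based CKD-EPI equation:
#' \deqn{eGFR = 141 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'   \max(Scr/\kappa, 1)^{-1.209} \cdot 0.993^{age} \cdot 1.018[female]}
#' with \eqn{\kappa = 0.7, \alpha = -0.329} for women and
#' \eqn{\kappa = 0.9, \alpha = -0.411} for men; serum creatinine is
#' converted from umol/L to mg/dL by dividing by 88.4. The race coefficient
#' is omitted (the cohorts this package targets exercise only the
#' non-Black branch).
#'
#' @param creatinine serum creatinine in umol/L.
#' @param age age in years.
#' @param sex `"male"` or `"female"` (vectorized).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
ckd_epi_egfr <- function(creatinine, age, sex) {
  if (any(!is.finite(creatinine) | creatinine <= 0)) {
    stop("creatinine must be > 0")
  }
  if (any(!is.finite(age) | age <= 0)) stop("age must be > 0")
  sex <- match.arg(tolower(sex), c("male", "female"), several.ok = TRUE)
  sex <- rep_len(sex, length(creatinine))
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  scr <- creatinine / 88.4
  r <- scr / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1)
}

#' Chronic kidney disease flag
#'
#' @param egfr eGFR in mL/min/1.73 m^2.
#' @return `TRUE` iff `egfr < 60` (strict).
#' @export
ckd_flag <- function(egfr) {
  if (any(!is.finite(egfr) | egfr < 0)) stop("egfr must be >= 0")
  egfr < 60
}

#' Follow-up time and event indicator from dates
#'
#' Follow-up runs from the discharge date to the first endpoint (event = 1)
#' or, for patients without an endpoint, to the last follow-up contact
#' (event = 0). Day differences are converted to months by dividing by
#' 30.4375 (the mean Gregorian month).
#'
#' @param cohort a `cohort` object from [load_cohort()] /
#'   [validate_cohort()], or its `data` data frame.
#' @return The input records augmented with `time_months` and `event`
#'   (0/1), minus any records whose computed time is not strictly positive;
#'   those are appended to the rejection report (attribute `rejected`).
#' @export
derive_time_to_event <- function(cohort) {
  d <- if (inherits(cohort, "cohort")) cohort$data else cohort
  ev <- d$event_occurred
  end <- as.Date(ifelse(ev, as.character(d$event_date),
                        as.character(d$last_contact_date)))
  days <- as.numeric(end - d$discharge_date)
  d$time_months <- days / MONTHS_DIVISOR
  d$event <- as.integer(ev)
  bad <- !is.finite(d$time_months) | d$time_months <= 0
  rejected <- data.frame(
    row = which(bad), patient_id = as.character(d$patient_id[bad]),
    reason = rep("non-positive follow-up time (same-day or pre-discharge endpoint)",
                 sum(bad)),
    stringsAsFactors = FALSE
  )
  out <- d[!bad, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Prepare a cohort for analysis
#'
#' Runs the full derivation chain on a validated cohort: BMI (where needed,
#' already handled at validation), CKD-EPI eGFR and CKD flag, follow-up
#' time/event, sex coded female = 0 / male = 1, and the six derived lipid
#' indices from [compute_indices()].
#'
#' @param cohort a `cohort` object or validated data frame.
#' @return Analysis-ready data frame; rejected-at-derivation rows are in
#'   attribute `rejected`.
#' @export
prepare_cohort <- function(cohort) {
  d <- derive_time_to_event(cohort)
  rej <- attr(d, "rejected")
  d$egfr <- ckd_epi_egfr(d$creatinine, d$age, d$sex)
  d$ckd <- ckd_flag(d$egfr)
  d$sex01 <- as.integer(d$sex == "male")
  idx <- compute_indices(tc = d$tc, tg = d$tg, hdl = d$hdl_c, ldl = d$ldl_c,
                         apob = d$apob, apoa1 = d$apoa1)
  d <- cbind(d, idx)
  attr(d, "rejected") <- rej
  d
}

#' Write a cohort CSV and JSON validation report
#'
#' @param cohort a `cohort` object.
#' @param path output CSV path for the validated records.
#' @param report_path optional path for a JSON validation report (row
#'   rejections with reasons); defaults to `path` with a
#'   `.validation.json` suffix.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, report_path = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  d <- cohort$data
  for (f in c("discharge_date", "event_date", "last_contact_date")) {
    d[[f]] <- as.character(d[[f]])
  }
  # doubles serialized at full precision so a load round-trips exactly
  for (f in names(d)) {
    if (is.double(d[[f]])) {
      num <- d[[f]]
      d[[f]] <- ifelse(is.na(num), NA_character_, sprintf("%.17g", num))
    }
  }
  write.csv(d, path, row.names = FALSE, na = "")
  if (is.null(report_path)) report_path <- paste0(path, ".validation.json")
  jsonlite::write_json(
    list(n_read = cohort$n_read, n_valid = nrow(cohort$data),
         rejected = cohort$rejected),
    report_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
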