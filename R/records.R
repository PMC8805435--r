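cohort_columns <- c(
  "patient_id", "age", "sex", "location", "tumor_size_cm",
  "mitoses_per_mm2", "ki67_li_pct", "necrosis_pct", "dedifferentiation",
  "follow_up_months", "metastasis", "time_to_metastasis_months"
)

sex_levels      <- c("male", "female")
location_levels <- c("intrathoracic", "intra_abdominal", "cns", "other")

#' Validate a patient-record cohort table
#'
#' Checks the cohort CSV schema: column set, covariate ranges, factor
#' levels, 0/1 indicators, and the event-time contract
#' (`time_to_metastasis_months` present and no later than
#' `follow_up_months` when `metastasis = 1`, blank otherwise).  Records
#' must be complete; no imputation of missing covariates is attempted.
#'
#' @param records Data frame with the cohort columns.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_patient_records <- function(records) {
  if (!is.data.frame(records)) {
    stop("records must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(cohort_columns, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_covariate(records$age, "age", lower = 0)
  check_covariate(records$tumor_size_cm, "tumor_size_cm",
                  lower = 0, lower_open = TRUE)
  check_covariate(records$mitoses_per_mm2, "mitoses_per_mm2", lower = 0)
  check_covariate(records$ki67_li_pct, "ki67_li_pct", lower = 0, upper = 100)
  check_covariate(records$necrosis_pct, "necrosis_pct", lower = 0, upper = 100)
  check_covariate(records$follow_up_months, "follow_up_months", lower = 0)
  check_indicator(records$metastasis, "metastasis")
  check_indicator(records$dedifferentiation, "dedifferentiation")
  check_enum(records$sex, "sex", sex_levels)
  check_enum(records$location, "location", location_levels)

  met  <- records$metastasis == 1
  ttm  <- records$time_to_metastasis_months
  if (any(met & is.na(ttm))) {
    stop("metastasis = 1 requires time_to_metastasis_months", call. = FALSE)
  }
  if (any(met & ttm > records$follow_up_months, na.rm = TRUE)) {
    stop("time_to_metastasis_months exceeds follow_up_months", call. = FALSE)
  }
  if (any(!met & !is.na(ttm))) {
    stop("time_to_metastasis_months must be blank when metastasis = 0",
         call. = FALSE)
  }
  records
}

check_indicator <- function(x, name) {
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop("'", name, "' must be 0/1 with no missing values", call. = FALSE)
  }
  invisible(x)
}

check_enum <- function(x, name, levels) {
  if (anyNA(x) || !all(x %in% levels)) {
    stop("'", name, "' must be one of: ", paste(levels, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Read and write the cohort CSV
#'
#' The cohort CSV has one header row and exactly the columns `patient_id`,
#' `age`, `sex`, `location`, `tumor_size_cm`, `mitoses_per_mm2`,
#' `ki67_li_pct`, `necrosis_pct`, `dedifferentiation`,
#' `follow_up_months`, `metastasis`, `time_to_metastasis_months`.
#' Booleans are encoded 0/1 and `time_to_metastasis_months` is blank for
#' patients without metastasis.  Reading validates the table; writing a
#' table read with `read_cohort_csv()` round-trips byte-identically.
#'
#' @param path File path.
#' @param records Validated cohort data frame.
#' @return `read_cohort_csv()` returns the validated data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(patient_id = "character"))
  validate_patient_records(records)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(records, path) {
  records <- validate_patient_records(records)
  utils::write.csv(records[, cohort_columns], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
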