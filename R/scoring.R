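#' Component scores for the SFT risk models
#'
#' Map raw clinicopathological covariates to the integer component scores
#' used by the Demicco risk models and their Ki-67-modified variants:
#'
#' * age: 0 for < 55 years, 1 for >= 55 years;
#' * tumor size: 0 for \[0, 5) cm, 1 for \[5, 10) cm, 2 for \[10, 15) cm,
#'   3 for >= 15 cm;
#' * mitotic frequency: 0 for exactly 0/mm2, 2 for >= 2/mm2, 1 for any
#'   positive rate below 2/mm2;
#' * Ki-67 labeling index: 0 for < 1%, 1 for \[1, 10)%, 2 for >= 10%;
#' * necrosis: 0 for < 10% of the tumor, 1 for >= 10%.
#'
#' Boundary values always take the higher score (55 years scores 1, 10%
#' Ki-67 scores 2, and so on).  All functions are vectorized and validate
#' their input: missing values and out-of-range covariates are errors, not
#' NA scores.
#'
#' @param age Patient age in years (non-negative).
#' @param tumor_size Maximum tumor diameter in cm (positive).
#' @param mitoses Mitotic figures per mm2 (non-negative; fractional rates
#'   are legitimate since counts are averaged over area).
#' @param ki67_li Ki-67 labeling index, percent in \[0, 100].
#' @param necrosis_percent Necrotic fraction of the tumor, percent in
#'   \[0, 100].
#' @param bins Score-bin definitions, see [risk_bins()].
#' @return Integer score vector of the same length as the input.
#' @examples
#' score_age(c(19, 54.9, 55, 82))
#' score_size(c(4.5, 5, 16))
#' score_ki67(c(0.5, 1, 9.9, 10, 72))
#' @export
score_age <- function(age, bins = risk_bins()) {
  check_covariate(age, "age", lower = 0)
  as.integer(age >= bins$age_threshold)
}

#' @rdname score_age
#' @export
score_size <- function(tumor_size, bins = risk_bins()) {
  check_covariate(tumor_size, "tumor_size", lower = 0, lower_open = TRUE)
  findInterval(tumor_size, bins$size_breaks)
}

#' @rdname score_age
#' @export
score_mitoses <- function(mitoses, bins = risk_bins()) {
  check_covariate(mitoses, "mitoses", lower = 0)
  ifelse(mitoses == 0, 0L, ifelse(mitoses >= bins$mitoses_upper, 2L, 1L))
}

#' @rdname score_age
#' @export
score_ki67 <- function(ki67_li, bins = risk_bins()) {
  check_covariate(ki67_li, "ki67_li", lower = 0, upper = 100)
  findInterval(ki67_li, bins$ki67_breaks)
}

#' @rdname score_age
#' @export
score_necrosis <- function(necrosis_percent, bins = risk_bins()) {
  check_covariate(necrosis_percent, "necrosis_percent", lower = 0, upper = 100)
  as.integer(necrosis_percent >= bins$necrosis_threshold)
}

check_covariate <- function(x, name, lower = -Inf, upper = Inf,
                            lower_open = FALSE) {
  if (!is.numeric(x)) {
    stop("'", name, "' must be numeric", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("'", name, "' contains missing values; records must be complete",
         call. = FALSE)
  }
  bad <- if (lower_open) x <= lower else x < lower
  bad <- bad | x > upper
  if (any(bad)) {
    stop("'", name, "' out of range: ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Total points and risk category for a cohort
#'
#' Sums the model's component scores for each patient and maps the total to
#' the published risk category.  Three-variable totals of 0-2 are low risk,
#' 3-4 intermediate and 5-6 high; four-variable totals of 0-3 are low, 4-5
#' intermediate and 6-7 high.  The dichotomized grouping collapses
#' intermediate and high into a single `intermediate_high` level, the
#' stratification under which two-group survival comparisons are run.
#'
#' @param records A patient-record data frame in the cohort CSV schema
#'   (see [read_cohort_csv()]); validated before scoring.
#' @param model One of `"demicco3"`, `"demicco4"`, `"modified3"`,
#'   `"modified4"` (see [risk_models()]).
#' @param bins Score-bin definitions, see [risk_bins()].
#' @return A data frame with one row per record: `patient_id`, `model`, the
#'   component scores used by the model (`age_score`, `size_score`, and
#'   `mitotic_score` or `ki67_score`, plus `necrosis_score` for the
#'   four-variable models), `total_points`, `category` (factor with levels
#'   low < intermediate < high) and `dichotomized` (factor low <
#'   intermediate_high).
#' @examples
#' rec <- data.frame(
#'   patient_id = "P1", age = 60, sex = "female", location = "other",
#'   tumor_size_cm = 16, mitoses_per_mm2 = 0, ki67_li_pct = 72,
#'   necrosis_pct = 20, dedifferentiation = 0L, follow_up_months = 24,
#'   metastasis = 1L, time_to_metastasis_months = 12
#' )
#' assign_risk(rec, "modified4")
#' @export
assign_risk <- function(records, model = risk_models(), bins = risk_bins()) {
  model <- match.arg(model)
  records <- validate_patient_records(records)

  scores <- data.frame(
    patient_id = records$patient_id,
    model      = model,
    age_score  = score_age(records$age, bins),
    size_score = score_size(records$tumor_size_cm, bins),
    stringsAsFactors = FALSE
  )
  if (model_uses_ki67(model)) {
    scores$ki67_score <- score_ki67(records$ki67_li_pct, bins)
    total <- scores$age_score + scores$size_score + scores$ki67_score
  } else {
    scores$mitotic_score <- score_mitoses(records$mitoses_per_mm2, bins)
    total <- scores$age_score + scores$size_score + scores$mitotic_score
  }
  if (model_uses_necrosis(model)) {
    scores$necrosis_score <- score_necrosis(records$necrosis_pct, bins)
    total <- total + scores$necrosis_score
  }
  scores$total_points <- as.integer(total)
  scores$category <- category_from_total(total, model, bins)
  scores$dichotomized <- dichotomize(scores$category)
  scores
}

category_from_total <- function(total, model, bins = risk_bins()) {
  cc <- if (model_uses_necrosis(model)) {
    bins$categories$four_variable
  } else {
    bins$categories$three_variable
  }
  lab <- ifelse(total <= cc$low_max, "low",
                ifelse(total <= cc$intermediate_max, "intermediate", "high"))
  factor(lab, levels = c("low", "intermediate", "high"), ordered = TRUE)
}

dichotomize <- function(category) {
  factor(ifelse(category == "low", "low", "intermediate_high"),
         levels = c("low", "intermediate_high"), ordered = TRUE)
}

#' Enumerate the full component-score space of a risk model
#'
#' Builds one row per element of the Cartesian product of the model's
#' component-score ranges (24 combinations for the three-variable models,
#' 48 for the four-variable ones), with the resulting total and risk
#' category.  Used to verify that the category bins tile the attainable
#' totals (0-6 or 0-7) exhaustively and unambiguously.
#'
#' @inheritParams assign_risk
#' @return A data frame of component scores plus `total_points`,
#'   `category` and `dichotomized`.
#' @examples
#' nrow(enumerate_score_space("demicco3"))   # 24
#' range(enumerate_score_space("modified4")$total_points)  # 0 7
#' @export
enumerate_score_space <- function(model = risk_models(), bins = risk_bins()) {
  model <- match.arg(model)
  prolif_name <- if (model_uses_ki67(model)) "ki67_score" else "mitotic_score"
  parts <- list(age_score = 0:1, size_score = 0:3)
  parts[[prolif_name]] <- 0:2
  if (model_uses_necrosis(model)) parts$necrosis_score <- 0:1
  space <- expand.grid(parts, KEEP.OUT.ATTRS = FALSE)
  space$total_points <- as.integer(rowSums(space))
  space$category <- category_from_total(space$total_points, model, bins)
  space$dichotomized <- dichotomize(space$category)
  space$model <- model
  space
}
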