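#' Ki-67 labeling index from labeled-nuclei counts
#'
#' The labeling index (LI) of a field is the percentage of tumor nuclei
#' staining positive for Ki-67: 100 * positive / (positive + negative).
#' The module works on nucleus counts produced by an image-analysis step
#' (only nuclear staining is counted); pixel-level analysis is out of
#' scope.
#'
#' @param fields Data frame with columns `field_id`, `positive`,
#'   `negative` (non-negative integer counts).
#' @return `field_li()` returns a numeric vector of percentages in
#'   \[0, 100], one per field.
#' @examples
#' f <- data.frame(field_id = "A", positive = 36, negative = 14)
#' field_li(f)   # 72
#' @export
field_li <- function(fields) {
  fields <- validate_fields(fields)
  100 * fields$positive / (fields$positive + fields$negative)
}

validate_fields <- function(fields) {
  if (!is.data.frame(fields)) stop("fields must be a data frame", call. = FALSE)
  need <- c("field_id", "positive", "negative")
  if (!all(need %in% names(fields))) {
    stop("fields need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(fields) == 0L) stop("no fields supplied", call. = FALSE)
  for (col in c("positive", "negative")) {
    x <- fields[[col]]
    if (anyNA(x) || !is.numeric(x) || any(x < 0) || any(x != round(x))) {
      stop("'", col, "' must be non-negative integer counts", call. = FALSE)
    }
  }
  if (any(fields$positive + fields$negative < 1)) {
    stop("labeling index undefined for empty fields", call. = FALSE)
  }
  fields
}

#' Select the hot-spot field
#'
#' The hot spot is the candidate field with the highest Ki-67 labeling
#' index among fields with at least `min_nuclei` counted tumor nuclei.
#' Ties are broken deterministically by `field_id` order so repeated runs
#' agree.
#'
#' @inheritParams field_li
#' @param min_nuclei Minimum nuclei per field for the field to be eligible
#'   (default 500).
#' @return The selected field as a one-row data frame with an `li` column
#'   appended.
#' @export
select_hotspot <- function(fields, min_nuclei = 500) {
  fields <- validate_fields(fields)
  li <- field_li(fields)
  eligible <- fields$positive + fields$negative >= min_nuclei
  if (!any(eligible)) {
    stop("no field has at least ", min_nuclei, " nuclei", call. = FALSE)
  }
  cand <- fields[eligible, , drop = FALSE]
  cand$li <- li[eligible]
  cand <- cand[order(-cand$li, cand$field_id), , drop = FALSE]
  out <- cand[1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ki-67 score from candidate fields
#'
#' Composition of hot-spot selection, labeling-index computation and the
#' three-level Ki-67 score (0 for < 1%, 1 for 1-10%, 2 for >= 10%).
#'
#' @inheritParams select_hotspot
#' @param bins Score-bin definitions, see [risk_bins()].
#' @return Integer score 0, 1 or 2.
#' @examples
#' f <- data.frame(field_id = c("A", "B"),
#'                 positive = c(12, 360), negative = c(988, 640))
#' ki67_score_from_fields(f)   # hotspot LI 36% -> score 2
#' @export
ki67_score_from_fields <- function(fields, min_nuclei = 500,
                                   bins = risk_bins()) {
  hotspot <- select_hotspot(fields, min_nuclei)
  score_ki67(hotspot$li, bins)
}

#' Read a labeled-nuclei field CSV
#'
#' Columns: `field_id`, `positive`, `negative`.
#'
#' @param path File path.
#' @return Validated fields data frame.
#' @export
read_fields_csv <- function(path) {
  fields <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(field_id = "character"))
  validate_fields(fields)
}
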