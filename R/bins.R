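#' Score-bin definitions for the risk models
#'
#' The four risk models (`demicco3`, `demicco4`, `modified3`, `modified4`)
#' share a common set of component cut-offs.  Those cut-offs are data, not
#' code: `risk_bins()` returns the published defaults and
#' `load_risk_bins()` reads an alternative definition from a JSON file with
#' the same structure, so variant cut-offs can be explored without touching
#' the scoring functions.
#'
#' All bins are half-open and closed below on the higher-score side: 55
#' years, 5/10/15 cm, 1%/10% Ki-67 and 10% necrosis each belong to the
#' higher-scoring bin.  The mitotic-frequency component is special-cased:
#' exactly 0/mm2 scores 0, anything at or above `mitoses_upper` (2/mm2)
#' scores 2, and every positive rate below that scores 1.
#'
#' @param path Path to a JSON file with the same fields as the default
#'   returned by `risk_bins()`.
#' @return A list with elements `age_threshold` (years), `size_breaks`
#'   (cm, ascending), `mitoses_upper` (count per mm2), `ki67_breaks`
#'   (percent, ascending), `necrosis_threshold` (percent) and `categories`
#'   (low/intermediate upper totals for the three- and four-variable
#'   models).
#' @examples
#' bins <- risk_bins()
#' bins$size_breaks
#' @export
risk_bins <- function() {
  list(
    age_threshold      = 55,
    size_breaks        = c(5, 10, 15),
    mitoses_upper      = 2,
    ki67_breaks        = c(1, 10),
    necrosis_threshold = 10,
    categories = list(
      three_variable = list(low_max = 2, intermediate_max = 4),
      four_variable  = list(low_max = 3, intermediate_max = 5)
    )
  )
}

#' @rdname risk_bins
#' @export
load_risk_bins <- function(path) {
  bins <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_risk_bins(bins)
  bins
}

validate_risk_bins <- function(bins) {
  need <- c("age_threshold", "size_breaks", "mitoses_upper", "ki67_breaks",
            "necrosis_threshold", "categories")
  missing <- setdiff(need, names(bins))
  if (length(missing) > 0) {
    stop("risk-bin definition lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot(
    is.numeric(bins$age_threshold), length(bins$age_threshold) == 1L,
    is.numeric(bins$size_breaks), !is.unsorted(bins$size_breaks, strictly = TRUE),
    is.numeric(bins$mitoses_upper), bins$mitoses_upper > 0,
    is.numeric(bins$ki67_breaks), length(bins$ki67_breaks) == 2L,
    !is.unsorted(bins$ki67_breaks, strictly = TRUE),
    is.numeric(bins$necrosis_threshold)
  )
  for (m in c("three_variable", "four_variable")) {
    cc <- bins$categories[[m]]
    if (is.null(cc$low_max) || is.null(cc$intermediate_max) ||
        cc$low_max >= cc$intermediate_max) {
      stop("invalid category cut-offs for ", m, call. = FALSE)
    }
  }
  invisible(bins)
}

#' Names of the supported risk models
#'
#' `demicco3` sums the age, size and mitotic-frequency scores;
#' `demicco4` adds the necrosis score.  The modified models substitute the
#' Ki-67 labeling-index score for the mitotic score: `modified3` sums age,
#' size and Ki-67, `modified4` adds necrosis.
#'
#' @return Character vector of the four model names.
#' @export
risk_models <- function() c("demicco3", "demicco4", "modified3", "modified4")

model_uses_necrosis <- function(model) model %in% c("demicco4", "modified4")
model_uses_ki67     <- function(model) model %in% c("modified3", "modified4")
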