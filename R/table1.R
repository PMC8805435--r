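#' Round half away from zero
#'
#' Clinical tables conventionally round 0.05 up to 0.1; base `round()`
#' rounds half to even.  Only used for display quantities.
#'
#' @param x Numeric vector (non-negative in this package's use).
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

table1_variables <- function(records, bins = risk_bins()) {
  strat <- list(
    "Age (years)" = cut_labels(score_age(records$age, bins),
                               c("< 55 (score 0)", ">= 55 (score 1)")),
    "Sex" = factor(records$sex, levels = sex_levels,
                   labels = c("Male", "Female")),
    "Location" = factor(records$location, levels = location_levels,
                        labels = c("IT", "IA", "CNS", "Other")),
    "Tumor size (cm)" = cut_labels(
      score_size(records$tumor_size_cm, bins),
      c("0-4.9 (score 0)", "5-9.9 (score 1)", "10-14.9 (score 2)",
        ">= 15 (score 3)")),
    "Mitoses/mm2" = cut_labels(
      score_mitoses(records$mitoses_per_mm2, bins),
      c("0 (score 0)", "0.5-1.5 (score 1)", ">= 2 (score 2)")),
    "Ki-67 LI (%)" = cut_labels(
      score_ki67(records$ki67_li_pct, bins),
      c("< 1 (score 0)", "1-10 (score 1)", ">= 10 (score 2)")),
    "Tumor necrosis (%)" = cut_labels(
      score_necrosis(records$necrosis_pct, bins),
      c("< 10 (score 0)", ">= 10 (score 1)")),
    "Dedifferentiation" = factor(records$dedifferentiation, levels = c(1, 0),
                                 labels = c("Present", "Absent"))
  )
  risk_blocks <- list(
    "Three-variable risk model" = list("demicco3", "category"),
    "Four-variable risk model" = list("demicco4", "category"),
    "Modified three-variable model" = list("modified3", "dichotomized"),
    "Modified four-variable model" = list("modified4", "dichotomized")
  )
  for (nm in names(risk_blocks)) {
    spec <- risk_blocks[[nm]]
    assignment <- assign_risk(records, spec[[1]], bins)
    col <- assignment[[spec[[2]]]]
    labels <- risk_level_labels(spec[[1]], spec[[2]])
    strat[[nm]] <- factor(as.character(col), levels = names(labels),
                          labels = unname(labels))
  }
  strat
}

cut_labels <- function(score, labels) {
  factor(score, levels = seq_along(labels) - 1L, labels = labels)
}

risk_level_labels <- function(model, by) {
  three <- !model_uses_necrosis(model)
  if (by == "category") {
    if (three) {
      c(low = "Low (0-2 points)", intermediate = "Intermediate (3-4 points)",
        high = "High (5-6 points)")
    } else {
      c(low = "Low (0-3 points)", intermediate = "Intermediate (4-5 points)",
        high = "High (6-7 points)")
    }
  } else {
    if (three) {
      c(low = "Low risk (0-2 points)",
        intermediate_high = "Intermediate/high risk (3-6 points)")
    } else {
      c(low = "Low risk (0-3 points)",
        intermediate_high = "Intermediate/high risk (4-7 points)")
    }
  }
}

#' Table-1-style cohort report
#'
#' One block per clinicopathological variable in the conventional order
#' (age, sex, location, tumor size, mitotic frequency, Ki-67 labeling
#' index, necrosis, dedifferentiation), followed by the four risk-model
#' stratifications (three-category for the Demicco models, dichotomized
#' low vs intermediate/high for the modified models).  Each row reports
#' the level's patient count, its percentage of the cohort (rounded half
#' up to one decimal), the five-year metastasis-free survival estimate
#' with its 95% confidence interval, and the log-rank p-value across the
#' variable's levels.
#'
#' A stratum with no events before 60 months reports 100% five-year MFS
#' with the confidence interval marked undefined (`ci_defined = FALSE`),
#' the "no events" footnote convention.  A variable with fewer than two
#' non-empty levels, or no events overall, gets `p_value = NA`.
#'
#' @param records Validated cohort data frame.
#' @param bins Score-bin definitions, see [risk_bins()].
#' @param conf_level Confidence level for the MFS band (default 0.95).
#' @param horizon_months Landmark for the survival column (default 60 =
#'   five years).
#' @return A data frame of class `table1` with columns `variable`,
#'   `level`, `count`, `percent`, `mfs`, `ci_lower`, `ci_upper`,
#'   `ci_defined`, `p_value`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 43, seed = 7))
#' t1 <- table1(cohort)
#' subset(t1, variable == "Modified three-variable model")
#' @export
table1 <- function(records, bins = risk_bins(), conf_level = 0.95,
                   horizon_months = 60) {
  records <- validate_patient_records(records)
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  samples <- mfs_dataset(records)
  strat <- table1_variables(records, bins)
  n <- nrow(records)

  blocks <- lapply(names(strat), function(var) {
    f <- strat[[var]]
    counts <- table(f)
    levels_present <- names(counts)[counts > 0]

    p_value <- NA_real_
    if (length(levels_present) >= 2L && any(samples$event)) {
      keep <- f %in% levels_present
      p_value <- logrank_test(samples$time[keep], samples$event[keep],
                              droplevels(f[keep]))$p_value
    }

    rows <- lapply(names(counts), function(lev) {
      in_lev <- f == lev
      mfs <- ci_lo <- ci_hi <- NA_real_
      ci_defined <- NA
      if (any(in_lev)) {
        fit <- km_estimate(samples$time[in_lev], samples$event[in_lev],
                           conf_level = conf_level)
        at <- survival_at(fit, horizon_months)
        mfs <- round_half_up(100 * at$surv, 1)
        ci_lo <- round_half_up(100 * at$lower, 1)
        ci_hi <- round_half_up(100 * at$upper, 1)
        ci_defined <- at$ci_defined
      }
      data.frame(
        variable = var, level = lev, count = as.integer(counts[[lev]]),
        percent = round_half_up(100 * counts[[lev]] / n, 1),
        mfs = mfs, ci_lower = ci_lo, ci_upper = ci_hi,
        ci_defined = ci_defined, p_value = p_value,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("table1", "data.frame")
  attr(out, "n") <- n
  out
}

#' Format a Table-1 report as Markdown
#'
#' Percentages and survival estimates are shown to one decimal, p-values
#' to three decimals with very small values floored at `< 0.001`.  Strata
#' with no events before the landmark show the interval as a footnote
#' marker (`a`); the footnote is appended below the table.
#'
#' @param t1 A [table1()] data frame.
#' @return Character vector of Markdown lines.
#' @export
format_table1_markdown <- function(t1) {
  stopifnot(inherits(t1, "table1"))
  fmt_p <- function(p, first) {
    ifelse(!first, "",
           ifelse(is.na(p), "NC",
                  ifelse(p < 0.0005, "<0.001", sprintf("%.3f", p))))
  }
  first_of_block <- !duplicated(t1$variable)
  empty <- is.na(t1$mfs)
  ci <- ifelse(empty, "",
        ifelse(!t1$ci_defined, "(a)",
        ifelse(is.na(t1$ci_lower), "-",
               sprintf("(%.1f-%.1f)", t1$ci_lower, t1$ci_upper))))
  mfs <- ifelse(empty, "-", sprintf("%.1f", t1$mfs))
  lines <- c(
    "| Variable | Level | Patients, n (%) | 5-year MFS (%) (95% CI) | Log-rank p |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %d (%.1f) | %s %s | %s |",
            ifelse(first_of_block, t1$variable, ""), t1$level,
            t1$count, t1$percent, mfs, ci,
            fmt_p(t1$p_value, first_of_block)),
    "",
    paste("(a) 95% CI not calculated because of no events until the",
          "landmark.  NC: not computable (degenerate stratification or",
          "no events).")
  )
  lines
}

#' @rdname format_table1_markdown
#' @param path Output file path.
#' @export
write_table1_csv <- function(t1, path) {
  stopifnot(inherits(t1, "table1"))
  utils::write.csv(as.data.frame(t1), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.table1 <- function(x, ...) {
  cat(format_table1_markdown(x), sep = "\n")
  invisible(x)
}
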