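#' Configuration for the synthetic SFT cohort generator
#'
#' The generator emulates the marginal covariate structure of a 43-patient
#' SFT surgical cohort and a two-group exponential survival model.  Default
#' category probabilities are the published cohort marginals (e.g. 24/43
#' patients aged >= 55, 6/43 tumors >= 15 cm, 4/43 with Ki-67 >= 10%);
#' covariates are sampled independently across variables (only marginals
#' are known), raw values uniformly within the sampled score bin with
#' open-ended bins truncated at age 95 years, size 25 cm, mitoses 10/mm2
#' and Ki-67 80%.  Follow-up is log-normal (median 43 months, mean about
#' 63) clamped to 1-250 months, matching the reported follow-up summary.
#' The metastasis hazard is exponential and depends on the covariates only
#' through the dichotomized risk group under `model`.
#'
#' @param n Cohort size (default 43).
#' @param seed Integer seed; the generator is fully reproducible.
#' @param p_age,p_size,p_mitoses,p_ki67,p_necrosis Category probabilities
#'   for the component scores (must each sum to 1).
#' @param p_sex,p_location Marginals for sex (male, female) and location
#'   (intrathoracic, intra_abdominal, cns, other).
#' @param p_dediff Probability of dedifferentiation (default 2/43).
#' @param hazard_low,hazard_high Exponential metastasis rates per month for
#'   the low and intermediate/high dichotomized groups.  Defaults (5e-4 and
#'   5e-3) give a low-risk group with essentially no events within five
#'   years and an elevated-risk group with roughly 74% five-year
#'   metastasis-free survival.
#' @param model Risk model whose dichotomization drives the hazard
#'   (default `"modified3"`).
#' @param followup_meanlog,followup_sdlog,followup_range Log-normal
#'   follow-up sampler (months) and clamping range.
#' @return A `sft_cohort_config` list.
#' @export
cohort_config <- function(n = 43, seed = 1,
                          p_age      = c(19, 24) / 43,
                          p_size     = c(24, 10, 3, 6) / 43,
                          p_mitoses  = c(34, 4, 5) / 43,
                          p_ki67     = c(15, 24, 4) / 43,
                          p_necrosis = c(40, 3) / 43,
                          p_sex      = c(21, 22) / 43,
                          p_location = c(10, 12, 6, 15) / 43,
                          p_dediff   = 2 / 43,
                          hazard_low = 5e-4, hazard_high = 5e-3,
                          model = "modified3",
                          followup_meanlog = log(43), followup_sdlog = 0.87,
                          followup_range = c(1, 250)) {
  config <- list(
    n = n, seed = seed,
    p_age = p_age, p_size = p_size, p_mitoses = p_mitoses,
    p_ki67 = p_ki67, p_necrosis = p_necrosis,
    p_sex = p_sex, p_location = p_location, p_dediff = p_dediff,
    hazard_low = hazard_low, hazard_high = hazard_high, model = model,
    followup_meanlog = followup_meanlog, followup_sdlog = followup_sdlog,
    followup_range = followup_range
  )
  validate_cohort_config(config)
  structure(config, class = "sft_cohort_config")
}

validate_cohort_config <- function(config) {
  if (config$n < 1) stop("cohort size must be at least 1", call. = FALSE)
  lens <- c(p_age = 2L, p_size = 4L, p_mitoses = 3L, p_ki67 = 3L,
            p_necrosis = 2L, p_sex = 2L, p_location = 4L)
  for (nm in names(lens)) {
    p <- config[[nm]]
    if (length(p) != lens[[nm]] || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8) {
      stop("'", nm, "' must be ", lens[[nm]],
           " non-negative probabilities summing to 1", call. = FALSE)
    }
  }
  if (config$p_dediff < 0 || config$p_dediff > 1) {
    stop("'p_dediff' must be a probability", call. = FALSE)
  }
  if (config$hazard_low < 0 || config$hazard_high < 0) {
    stop("hazards must be non-negative", call. = FALSE)
  }
  if (!config$model %in% risk_models()) {
    stop("unknown risk model '", config$model, "'", call. = FALSE)
  }
  invisible(config)
}

#' @rdname cohort_config
#' @param path JSON file with any subset of the `cohort_config()` arguments.
#' @export
load_cohort_config <- function(path) {
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(cohort_config, args)
}

# raw-value bins per component score as (lower, upper, recorded cap);
# open-ended bins truncated at plausible clinical bounds.  Values are
# recorded to one decimal, so bins with an exclusive upper cut-off cap the
# recorded value at cut-off - 0.1 to keep rounding inside the bin.
value_bins <- list(
  age      = list(c(19, 55, 54.9), c(55, 95, 95)),
  size     = list(c(1, 5, 4.9), c(5, 10, 9.9), c(10, 15, 14.9),
                  c(15, 25, 25)),
  mitoses  = list(c(0, 0, 0), c(0.5, 1.5, 1.5), c(2, 10, 10)),
  ki67     = list(c(0, 1, 0.9), c(1, 10, 9.9), c(10, 80, 80)),
  necrosis = list(c(0, 10, 9.9), c(10, 100, 100))
)

sample_within_bins <- function(score, bins) {
  lo  <- vapply(bins, `[`, numeric(1), 1L)[score + 1L]
  hi  <- vapply(bins, `[`, numeric(1), 2L)[score + 1L]
  cap <- vapply(bins, `[`, numeric(1), 3L)[score + 1L]
  pmin(round(stats::runif(length(score), lo, hi), 1), cap)
}

#' Generate a synthetic SFT cohort
#'
#' Draws `config$n` patient records: component-score categories from the
#' configured marginals, raw covariate values uniformly within the sampled
#' bin, a log-normal administrative follow-up, and an exponential
#' metastasis time whose rate is `hazard_low` or `hazard_high` according
#' to the record's dichotomized risk group under `config$model`.
#' Metastases after the follow-up horizon are censored.  Identical
#' configurations (including seed) reproduce the cohort byte-for-byte in
#' CSV form.
#'
#' @param config A [cohort_config()] object.
#' @return A validated cohort data frame in the cohort CSV schema.
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 43, seed = 7))
#' table(assign_risk(cohort, "modified3")$category)
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  n <- config$n
  set.seed(config$seed)

  draw <- function(p) sample.int(length(p), n, replace = TRUE, prob = p) - 1L
  age_s  <- draw(config$p_age)
  size_s <- draw(config$p_size)
  mit_s  <- draw(config$p_mitoses)
  ki_s   <- draw(config$p_ki67)
  nec_s  <- draw(config$p_necrosis)

  records <- data.frame(
    patient_id = sprintf("SFT%04d", seq_len(n)),
    age = sample_within_bins(age_s, value_bins$age),
    sex = sex_levels[draw(config$p_sex) + 1L],
    location = location_levels[draw(config$p_location) + 1L],
    tumor_size_cm   = sample_within_bins(size_s, value_bins$size),
    mitoses_per_mm2 = sample_within_bins(mit_s, value_bins$mitoses),
    ki67_li_pct     = sample_within_bins(ki_s, value_bins$ki67),
    necrosis_pct    = sample_within_bins(nec_s, value_bins$necrosis),
    dedifferentiation = as.integer(stats::runif(n) < config$p_dediff),
    stringsAsFactors = FALSE
  )

  follow_up <- pmin(pmax(
    stats::rlnorm(n, config$followup_meanlog, config$followup_sdlog),
    config$followup_range[1]), config$followup_range[2])
  records$follow_up_months <- round(follow_up, 1)

  records$metastasis <- 0L
  records$time_to_metastasis_months <- NA_real_
  risk <- assign_risk(records, config$model)
  rate <- ifelse(risk$dichotomized == "low",
                 config$hazard_low, config$hazard_high)
  ttm <- ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-300)), Inf)
  is_event <- ttm <= records$follow_up_months
  records$metastasis <- as.integer(is_event)
  records$time_to_metastasis_months <-
    ifelse(is_event, pmax(round(ttm, 1), 0.1), NA_real_)

  validate_patient_records(records)
}

#' Generate labeled-nuclei candidate fields
#'
#' Simulates Ki-67 counting fields for the quantifier: each field draws a
#' binomial number of positive nuclei at rate `true_li`/100, with the
#' first field designated the hot spot at rate
#' min(100, `true_li` * `hotspot_boost`)/100.
#'
#' @param true_li Background Ki-67 labeling index, percent in \[0, 100].
#' @param n_fields Number of candidate fields (default 10).
#' @param nuclei_per_field Tumor nuclei counted per field (default 1000).
#' @param hotspot_boost Multiplier on the hot-spot field's rate (default 1
#'   = all fields exchangeable).
#' @param seed Integer seed.
#' @return Fields data frame (`field_id`, `positive`, `negative`) with the
#'   hot spot as `F01`.
#' @export
generate_fields <- function(true_li, n_fields = 10, nuclei_per_field = 1000,
                            hotspot_boost = 1, seed = 1) {
  if (is.na(true_li) || true_li < 0 || true_li > 100) {
    stop("true_li must be a percent in [0, 100]", call. = FALSE)
  }
  if (n_fields < 1 || nuclei_per_field < 1 || hotspot_boost < 0) {
    stop("invalid field-generation parameters", call. = FALSE)
  }
  set.seed(seed)
  rates <- rep(true_li / 100, n_fields)
  rates[1L] <- min(100, true_li * hotspot_boost) / 100
  positive <- stats::rbinom(n_fields, nuclei_per_field, rates)
  data.frame(
    field_id = sprintf("F%02d", seq_len(n_fields)),
    positive = positive,
    negative = nuclei_per_field - positive,
    stringsAsFactors = FALSE
  )
}
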