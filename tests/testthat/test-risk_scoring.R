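test_that("component scores honour the published cut-offs and boundaries", {
  # boundaries belong to the higher-scoring bin
  expect_identical(score_age(c(0, 19, 54.9, 55, 82)), c(0L, 0L, 0L, 1L, 1L))
  expect_equal(score_size(c(0.1, 4.5, 4.95, 5, 9.9, 10, 14.9, 15, 16)),
               c(0L, 0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_identical(score_mitoses(c(0, 0.3, 0.5, 1, 1.5, 1.7, 2, 8)),
                   c(0L, 1L, 1L, 1L, 1L, 1L, 2L, 2L))
  expect_equal(score_ki67(c(0, 0.5, 0.99, 1, 9.9, 10, 72, 100)),
               c(0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(score_necrosis(c(0, 9.9, 10, 100)), c(0L, 0L, 1L, 1L))
})

test_that("out-of-range and missing covariates are rejected", {
  expect_error(score_age(-1), "out of range")
  expect_error(score_size(0), "out of range")
  expect_error(score_mitoses(-0.5), "out of range")
  expect_error(score_ki67(101), "out of range")
  expect_error(score_necrosis(-2), "out of range")
  expect_error(score_age(NA_real_), "missing")
})

test_that("assign_risk sums the model's components and bins the total", {
  rec <- make_record(age = 60, tumor_size_cm = 16, ki67_li_pct = 72,
                     mitoses_per_mm2 = 3, necrosis_pct = 20)
  m3 <- assign_risk(rec, "modified3")
  expect_equal(m3$total_points, 6L)   # 1 + 3 + 2
  expect_equal(as.character(m3$category), "high")

  m4 <- assign_risk(rec, "modified4")
  expect_equal(m4$total_points, 7L)   # attainable maximum
  expect_equal(as.character(m4$category), "high")
  expect_equal(as.character(m4$dichotomized), "intermediate_high")

  zero <- assign_risk(make_record(age = 20, tumor_size_cm = 2,
                                  mitoses_per_mm2 = 0), "demicco3")
  expect_equal(zero$total_points, 0L)
  expect_equal(as.character(zero$category), "low")
  expect_equal(as.character(zero$dichotomized), "low")
})

test_that("assign_risk is deterministic and four-variable totals add necrosis", {
  set.seed(11)
  cohort <- generate_cohort(cohort_config(n = 60, seed = 11))
  for (pair in list(c("demicco3", "demicco4"), c("modified3", "modified4"))) {
    a3 <- assign_risk(cohort, pair[1])
    a4 <- assign_risk(cohort, pair[2])
    expect_equal(a4$total_points, a3$total_points + a4$necrosis_score)
    expect_identical(a3, assign_risk(cohort, pair[1]))  # pure function
  }
})

test_that("score space enumeration is exhaustive for all four models", {
  for (model in risk_models()) {
    space <- enumerate_score_space(model)
    four <- model %in% c("demicco4", "modified4")
    expect_equal(nrow(space), if (four) 48L else 24L)
    expect_equal(range(space$total_points), c(0L, if (four) 7L else 6L))
    # every attainable total maps to exactly one category
    map <- unique(space[, c("total_points", "category")])
    expect_equal(nrow(map), length(unique(space$total_points)))
    expect_false(anyNA(space$category))
    # dichotomized = low iff category = low, over the whole space
    expect_equal(space$dichotomized == "low", space$category == "low")
  }
})

test_that("raising any covariate never lowers total points or category", {
  set.seed(202)
  raise <- function(rec, what) {
    bump <- runif(1, 0.1, 30)
    rec[[what]] <- switch(what,
      age = min(rec[[what]] + bump, 95),
      tumor_size_cm = min(rec[[what]] + bump, 25),
      mitoses_per_mm2 = min(rec[[what]] + bump, 10),
      ki67_li_pct = min(rec[[what]] + bump, 100),
      necrosis_pct = min(rec[[what]] + bump, 100))
    rec
  }
  covs <- c("age", "tumor_size_cm", "mitoses_per_mm2", "ki67_li_pct",
            "necrosis_pct")
  for (i in 1:60) {
    base <- make_record(
      age = runif(1, 19, 90), tumor_size_cm = runif(1, 0.5, 24),
      mitoses_per_mm2 = runif(1, 0, 9), ki67_li_pct = runif(1, 0, 95),
      necrosis_pct = runif(1, 0, 95))
    for (model in risk_models()) {
      before <- assign_risk(base, model)
      for (what in covs) {
        after <- assign_risk(raise(base, what), model)
        expect_gte(after$total_points, before$total_points)
        expect_true(after$category >= before$category)
      }
    }
  }
})

test_that("bin definitions load from the shipped JSON config", {
  path <- system.file("extdata", "risk_bins.json", package = "sftrisk")
  bins <- load_risk_bins(path)
  expect_equal(bins[names(risk_bins())], risk_bins())
  # a variant config changes the scoring without touching code
  alt <- risk_bins()
  alt$age_threshold <- 60
  expect_identical(score_age(57, alt), 0L)
})

test_that("cohort CSV round-trips and rejects incomplete records", {
  cohort <- generate_cohort(cohort_config(n = 20, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(back, cohort)
  # second write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))

  bad <- cohort
  bad$time_to_metastasis_months[bad$metastasis == 0][1] <- 10
  expect_error(validate_patient_records(bad), "blank")
  bad2 <- cohort[, -2]
  expect_error(validate_patient_records(bad2), "lacks column")
  bad3 <- make_record(metastasis = 1L, time_to_metastasis_months = 60,
                      follow_up_months = 48)
  expect_error(validate_patient_records(bad3), "exceeds")
})
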