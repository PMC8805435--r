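test_that("product-limit estimate matches hand-computed small cases", {
  # single subject with an event: S drops to 0 at t = 10
  one <- km_estimate(10, TRUE)
  expect_equal(one$time, 10)
  expect_equal(one$surv, 0)

  # all censored: no event times, S = 1 throughout
  flat <- km_estimate(c(4, 9, 30), c(FALSE, FALSE, FALSE))
  expect_length(flat$time, 0L)
  expect_equal(survival_at(flat, 60)$surv, 1)

  # event at 5 (n = 3), censored at 8, event at 12 (n = 1):
  # S(5) = 2/3, S(12) = 2/3 * (1 - 1/1) = 0
  fit <- km_estimate(c(5, 8, 12), c(TRUE, FALSE, TRUE))
  expect_equal(fit$surv, c(2 / 3, 0))
  expect_equal(fit$n_risk, c(3, 1))
  # Greenwood at first event time: S^2 * d/(n(n-d)) = (2/3)^2 * 1/6
  expect_equal(fit$greenwood_var[1], (2 / 3)^2 / 6)

  # censoring tied with an event keeps the censored subject at risk
  tied <- km_estimate(c(5, 5, 10), c(TRUE, FALSE, TRUE))
  expect_equal(tied$n_risk, c(3, 1))
  expect_equal(tied$surv, c(2 / 3, 0))
})

test_that("with no censoring the estimate is the empirical survivor function", {
  set.seed(31)
  for (i in 1:10) {
    t <- round(rexp(40, 0.04), 2) + 0.01
    fit <- km_estimate(t, rep(TRUE, 40))
    ecdf_surv <- vapply(fit$time, function(x) mean(t > x), numeric(1))
    expect_equal(fit$surv, ecdf_surv)
  }
})

test_that("step evaluation is right-continuous with the no-events convention", {
  fit <- km_estimate(c(30, 70), c(TRUE, FALSE))
  at60 <- survival_at(fit, 60)
  expect_equal(at60$surv, 0.5)
  expect_true(at60$ci_defined)

  # just before the first event: S = 1, CI flagged undefined
  before <- survival_at(fit, 29.9)
  expect_equal(before$surv, 1)
  expect_false(before$ci_defined)
  expect_true(is.na(before$lower))
  expect_equal(survival_at(fit, 0)$surv, 1)
  expect_equal(survival_at(fit, 30)$surv, 0.5)  # right-continuous at the jump

  expect_error(survival_at(fit, -1), "non-negative")
  expect_error(km_estimate(numeric(0), logical(0)), "no survival samples")
  expect_error(km_estimate(c(3, 0), c(TRUE, TRUE)), "positive")
})

test_that("Greenwood accumulation is zero before events and non-decreasing", {
  set.seed(77)
  fx <- random_survival_fixture(80)
  fit <- km_estimate(fx$time, fx$event)
  gw_cum <- fit$greenwood_var / fit$surv^2
  ok <- is.finite(gw_cum)
  expect_true(all(diff(gw_cum[ok]) >= 0))
  expect_true(all(gw_cum[ok] > 0))
  # confidence band brackets the estimate wherever defined
  def <- !is.na(fit$lower)
  expect_true(all(fit$lower[def] <= fit$surv[def] + 1e-12))
  expect_true(all(fit$upper[def] >= fit$surv[def] - 1e-12))
})

test_that("log-rank test has the symmetry and invariance properties", {
  set.seed(13)
  t <- round(rexp(25, 0.03), 2) + 0.01
  e <- runif(25) < 0.7
  # identical risk experience in both groups: statistic 0, p = 1
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 25))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # label swap leaves statistic and p unchanged
  fx <- random_survival_fixture(60)
  grp <- rep(c("x", "y"), 30)
  lr1 <- logrank_test(fx$time, fx$event, grp)
  lr2 <- logrank_test(fx$time, fx$event, ifelse(grp == "x", "y", "x"))
  expect_equal(lr1$statistic, lr2$statistic)
  expect_equal(lr1$p_value, lr2$p_value)
  expect_equal(sum(lr1$groups$observed), sum(lr1$groups$expected))

  expect_error(logrank_test(fx$time, fx$event, rep("x", 60)), "two")
  expect_error(logrank_test(c(5, 7), c(FALSE, FALSE), c("a", "b")),
               "zero events")
})

test_that("two-group statistic matches a brute-force hypergeometric oracle", {
  set.seed(29)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    fx <- random_survival_fixture(n)
    grp <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(grp)) < 2 || !any(fx$event)) next
    lr <- logrank_test(fx$time, fx$event, grp)
    expect_equal(lr$statistic,
                 brute_force_logrank_2g(fx$time, fx$event, grp),
                 tolerance = 1e-10)
  }
})

test_that("metastasis-free survival mapping censors non-events at follow-up", {
  rec <- rbind(
    make_record(patient_id = "A", follow_up_months = 43),
    make_record(patient_id = "B", metastasis = 1L,
                time_to_metastasis_months = 12, follow_up_months = 30)
  )
  samples <- mfs_dataset(rec)
  expect_equal(nrow(samples), 2L)
  expect_equal(samples$time, c(43, 12))
  expect_equal(samples$event, c(FALSE, TRUE))

  cohort <- generate_cohort(cohort_config(n = 43, seed = 2))
  expect_equal(nrow(mfs_dataset(cohort)), 43L)  # bijection

  expect_error(mfs_dataset(make_record(follow_up_months = 0)),
               "positive")
})
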