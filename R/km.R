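#' Kaplan-Meier product-limit estimate with Greenwood variance
#'
#' From-scratch product-limit estimator of the survivor function.  At each
#' distinct event time t_i with n_i subjects at risk and d_i events,
#' S(t_i) = prod_{j <= i} (1 - d_j / n_j), and the Greenwood variance is
#' Var S(t) = S(t)^2 * sum_{j: t_j <= t} d_j / (n_j (n_j - d_j)).
#' Ties between events and censorings at the same time are resolved with
#' events first (a subject censored at t is still at risk at t).
#'
#' Pointwise confidence bands use the complementary log-log transform by
#' default (limits S^exp(± z * se(log(-log S)))), which keeps the band in
#' \[0, 1]; `conf_type = "plain"` gives the linear Greenwood band.  The
#' band is undefined where S is 0 or 1.
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicator: `TRUE`/1 = event observed, `FALSE`/0 =
#'   censored.
#' @param conf_level Coverage of the pointwise band (default 0.95).
#' @param conf_type `"log-log"` (default) or `"plain"`.
#' @return An object of class `km_curve`: a list with `time` (distinct
#'   event times), `n_risk`, `n_event`, `surv`, `greenwood_var`, `lower`,
#'   `upper`, and bookkeeping fields (`n`, `n_events`, `conf_level`,
#'   `conf_type`).
#' @examples
#' fit <- km_estimate(c(5, 8, 12), c(TRUE, FALSE, TRUE))
#' fit$surv   # 2/3 at t = 5, 0 at t = 12
#' @seealso [survival_at()] for step-function evaluation at a time point.
#' @export
km_estimate <- function(time, event, conf_level = 0.95,
                        conf_type = c("log-log", "plain")) {
  conf_type <- match.arg(conf_type)
  if (length(time) == 0L) stop("no survival samples", call. = FALSE)
  if (anyNA(time) || anyNA(event)) {
    stop("missing values in survival samples", call. = FALSE)
  }
  if (!is.numeric(time) || any(time <= 0)) {
    stop("survival times must be positive", call. = FALSE)
  }
  event <- as.logical(event)
  if (!(conf_level > 0 && conf_level < 1)) {
    stop("conf_level must be in (0, 1)", call. = FALSE)
  }

  tt <- sort(unique(time[event]))
  n_risk  <- vapply(tt, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(time == t & event), numeric(1))

  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood accumulator; the d = n step drives S to 0 and the variance of
  # a point mass at 0 is undefined (NaN), matching standard practice.
  gw_terms <- ifelse(n_risk > n_event,
                     n_event / (n_risk * (n_risk - n_event)), NaN)
  gw_cum <- cumsum(gw_terms)
  greenwood_var <- surv^2 * gw_cum

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ok <- is.finite(greenwood_var) & surv > 0 & surv < 1
  lower <- upper <- rep(NA_real_, length(surv))
  if (conf_type == "log-log") {
    se_cll <- sqrt(gw_cum[ok]) / abs(log(surv[ok]))
    lower[ok] <- surv[ok]^exp(z * se_cll)
    upper[ok] <- surv[ok]^exp(-z * se_cll)
  } else {
    half <- z * sqrt(greenwood_var[ok])
    lower[ok] <- pmax(0, surv[ok] - half)
    upper[ok] <- pmin(1, surv[ok] + half)
  }

  structure(
    list(time = tt, n_risk = n_risk, n_event = n_event, surv = surv,
         greenwood_var = greenwood_var, lower = lower, upper = upper,
         n = length(time), n_events = sum(event),
         conf_level = conf_level, conf_type = conf_type),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", x$n_events, "events\n")
  if (length(x$time) == 0L) {
    cat("no events observed; S(t) = 1 throughout follow-up\n")
  } else {
    print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                     surv = round(x$surv, 4),
                     lower = round(x$lower, 4), upper = round(x$upper, 4)))
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Metastasis-free survival",
                          xmax = NULL, ...) {
  tmax <- if (is.null(xmax)) max(x$time, 1) * 1.05 else xmax
  steps_x <- c(0, rep(x$time, each = 2), tmax)
  steps_y <- c(1, 1, rep(x$surv, each = 2))[seq_along(steps_x)]
  plot(steps_x, steps_y, type = "l", ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation of the product-limit estimate,
#' with the pointwise confidence band.  When no event has occurred at or
#' before `t` the estimate is exactly 1 by construction and no variance is
#' available, so the interval is flagged undefined -- the same convention
#' as a cohort table that reports 100% five-year metastasis-free survival
#' with a "no events" footnote instead of an interval.
#'
#' @param curve A [km_estimate()] fit.
#' @param t Non-negative time (months); vectorized.
#' @return A data frame with one row per `t`: `time`, `surv`, `lower`,
#'   `upper`, `ci_defined` (FALSE iff no events at or before `t`).
#' @examples
#' fit <- km_estimate(c(30, 70), c(TRUE, FALSE))
#' survival_at(fit, 60)$surv   # 0.5
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (anyNA(t) || !is.numeric(t) || any(t < 0)) {
    stop("evaluation times must be non-negative", call. = FALSE)
  }
  idx <- findInterval(t, curve$time)
  has_event <- idx >= 1L
  pick <- function(field, default) {
    ifelse(has_event, field[pmax(idx, 1L)], default)
  }
  data.frame(
    time = t,
    surv = pick(curve$surv, 1),
    lower = pick(curve$lower, NA_real_),
    upper = pick(curve$upper, NA_real_),
    ci_defined = has_event
  )
}

#' Build metastasis-free-survival samples from patient records
#'
#' Maps each patient to a (time, event) pair for the metastasis-free
#' survival endpoint: patients with metastasis contribute an event at
#' `time_to_metastasis_months`; all others -- including deaths without
#' documented metastasis -- are censored at `follow_up_months`.
#'
#' @param records Validated cohort data frame (see
#'   [validate_patient_records()]).
#' @return Data frame with columns `patient_id`, `time` (months) and
#'   `event` (logical).
#' @export
mfs_dataset <- function(records) {
  records <- validate_patient_records(records)
  event <- records$metastasis == 1
  time <- ifelse(event, records$time_to_metastasis_months,
                 records$follow_up_months)
  if (any(time <= 0)) {
    stop("non-positive follow-up or event time; times are months since ",
         "resection/biopsy and must be positive", call. = FALSE)
  }
  data.frame(patient_id = records$patient_id, time = time, event = event,
             stringsAsFactors = FALSE)
}
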