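#' Log-rank test for two or more groups
#'
#' Standard (unweighted) log-rank test, implemented from first principles.
#' At each pooled distinct event time t_j with d_j total events among n_j
#' subjects at risk, group g's expected count is d_j * n_gj / n_j and the
#' covariance of the observed counts is the multivariate hypergeometric
#' one:
#' V_ghj = d_j (n_j - d_j) / (n_j - 1) * (n_gj / n_j) (1\{g = h\} - n_hj / n_j).
#' The statistic is the quadratic form of the summed (O - E) vector over
#' the first k - 1 groups against the summed covariance, and the p-value
#' comes from the chi-square upper tail on k - 1 degrees of freedom.  With
#' two groups this reduces to the familiar (O - E)^2 / V.
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicator (TRUE/1 = event, FALSE/0 = censored).
#' @param group Group label per subject; at least two non-empty groups and
#'   at least one event overall are required.
#' @return An object of class `logrank_test`: `statistic`, `df`,
#'   `p_value`, and a per-group table `groups` with `n`, `observed` and
#'   `expected` event counts.
#' @examples
#' set.seed(1)
#' t1 <- rexp(30, 0.05); t2 <- rexp(30, 0.15)
#' lr <- logrank_test(c(t1, t2), rep(TRUE, 60), rep(c("a", "b"), each = 30))
#' lr$p_value
#' @export
logrank_test <- function(time, event, group) {
  if (anyNA(time) || anyNA(event) || anyNA(group)) {
    stop("missing values in log-rank input", call. = FALSE)
  }
  if (!is.numeric(time) || any(time <= 0)) {
    stop("survival times must be positive", call. = FALSE)
  }
  event <- as.logical(event)
  group <- factor(group)
  group <- droplevels(group)
  k <- nlevels(group)
  if (k < 2L) stop("log-rank test needs at least two non-empty groups",
                   call. = FALSE)
  if (!any(event)) stop("log-rank statistic undefined with zero events",
                        call. = FALSE)

  tt <- sort(unique(time[event]))
  m <- length(tt)
  at_risk <- outer(time, tt, `>=`)                       # n x m
  n_j  <- colSums(at_risk)
  # per-group at-risk and observed-event counts at each pooled event time
  gmat <- stats::model.matrix(~ group - 1)               # n x k
  n_gj <- t(gmat) %*% at_risk                            # k x m
  is_event_at <- outer(time, tt, `==`) & event
  d_gj <- t(gmat) %*% is_event_at                        # k x m
  d_j  <- colSums(d_gj)

  e_gj <- sweep(n_gj, 2, d_j / n_j, `*`)
  observed <- rowSums(d_gj)
  expected <- rowSums(e_gj)

  # summed hypergeometric covariance over the first k-1 groups
  mult <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  p_gj <- sweep(n_gj, 2, n_j, `/`)                       # k x m
  V <- matrix(0, k - 1L, k - 1L)
  for (g in seq_len(k - 1L)) {
    for (h in seq_len(g)) {
      vj <- mult * p_gj[g, ] * ((g == h) - p_gj[h, ])
      V[g, h] <- V[h, g] <- sum(vj)
    }
  }
  z <- (observed - expected)[seq_len(k - 1L)]
  statistic <- drop(z %*% pseudo_solve(V) %*% z)
  statistic <- max(statistic, 0)
  p_value <- stats::pchisq(statistic, df = k - 1L, lower.tail = FALSE)

  structure(
    list(statistic = statistic, df = k - 1L, p_value = p_value,
         groups = data.frame(group = levels(group),
                             n = as.vector(table(group)),
                             observed = observed, expected = expected,
                             row.names = NULL)),
    class = "logrank_test"
  )
}

# Moore-Penrose inverse via SVD; the summed covariance can be singular when
# a group runs out of risk set early.
pseudo_solve <- function(V, tol = 1e-12) {
  if (length(V) == 1L) {
    return(matrix(if (V > tol) 1 / V else 0, 1L, 1L))
  }
  s <- svd(V)
  pos <- s$d > tol * max(s$d, tol)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test: chi-square =", format(x$statistic, digits = 5),
      "on", x$df, "df, p =", format.pval(x$p_value, digits = 3), "\n")
  print(x$groups)
  invisible(x)
}
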