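# Shared fixture builders; everything is generated in code.

# one complete patient record with overridable fields
make_record <- function(..., n = 1L) {
  rec <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = 40, sex = "female", location = "other",
    tumor_size_cm = 3, mitoses_per_mm2 = 0, ki67_li_pct = 0.5,
    necrosis_pct = 0, dedifferentiation = 0L,
    follow_up_months = 48, metastasis = 0L,
    time_to_metastasis_months = NA_real_,
    stringsAsFactors = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) rec[[nm]] <- overrides[[nm]]
  rec
}

# random censored survival fixture for oracle comparisons
random_survival_fixture <- function(n, rate = 0.05, cens_range = c(1, 120)) {
  latent <- rexp(n, rate)
  cens <- runif(n, cens_range[1], cens_range[2])
  data.frame(time = round(pmin(latent, cens), 2) + 0.01,
             event = latent <= cens)
}

# independent brute-force log-rank oracle for two groups: plain loops and
# explicit hypergeometric moments, structured nothing like the package code
brute_force_logrank_2g <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    n_t <- sum(time >= t)
    n1_t <- sum(time >= t & g1)
    d_t <- sum(time == t & event)
    d1_t <- sum(time == t & event & g1)
    o_minus_e <- o_minus_e + d1_t - d_t * n1_t / n_t
    if (n_t > 1) {
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  (o_minus_e^2) / v
}
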