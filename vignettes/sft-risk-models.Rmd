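---
title: "Methods: point-based SFT risk models, Ki-67 quantification and survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-based SFT risk models, Ki-67 quantification and survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sftrisk)
```

## The scoring models

Solitary fibrous tumor (SFT) risk stratification by the Demicco point
models sums integer component scores: patient age (0 for < 55 years, 1
for ≥ 55), tumor size (0/1/2/3 for the 5-cm bands up to ≥ 15 cm) and
mitotic frequency (0 for 0/mm², 1 below 2/mm², 2 at or above), with the
four-variable model adding necrosis (1 for ≥ 10% of the tumor).  The
modified models substitute a Ki-67 labeling-index (LI) score (0 for
< 1%, 1 for 1–10%, 2 for ≥ 10%) for the mitotic score, on the grounds
that image-analysis Ki-67 measurement is more reproducible than mitotic
counting.  Three-variable totals of 0–2/3–4/5–6 and four-variable totals
of 0–3/4–5/6–7 map to low/intermediate/high risk; the dichotomization
collapses intermediate and high.

Three boundary conventions deserve explicit statement, because the
published bin labels are written in the "0–4.9 cm" style:

* **All bins are half-open, closed below on the higher-score side.**  A
  55-year-old scores 1, a 10% LI scores 2, a 15-cm tumor scores 3; and
  "0–4.9 cm" is read as [0, 5), so a 4.95-cm tumor scores 0 rather than
  falling between bins.  Writing upper edges as x.9 implies the next bin
  begins at the round number.
* **The mitotic gap.**  The printed mitotic bins (0, 0.5–1.5, ≥ 2 per
  mm²) do not tile the line: nothing is said about e.g. 0.3 or 1.7/mm²,
  values that arise naturally when counts are averaged over several mm².
  We score any positive rate below 2/mm² as 1.  This preserves the three
  printed anchors, keeps the score monotone in the rate, and never
  creates an unscorable patient.  Fractional rates are accepted as input
  for the same reason the published bin "0.5–1.5/mm²" is fractional.
* **Completeness is required.**  Missing covariates are rejected rather
  than imputed; a record must be complete for the requested model.

The cut-offs themselves are data, not code: `risk_bins()` returns the
default definition and `load_risk_bins()` reads the same structure from
JSON (a copy ships in `inst/extdata/risk_bins.json`), so variant
cut-offs can be explored without touching the scoring functions.
`enumerate_score_space()` enumerates the full component product space
(24 or 48 combinations) and is the oracle used to verify that every
attainable total (0–6 or 0–7) maps to exactly one category and that
category is monotone in the total.

## Ki-67 hot-spot quantification

The quantifier operates on labeled-nuclei counts per candidate field
(positive and negative tumor nuclei), not on pixels: segmentation and
stain classification are upstream concerns of the image-analysis
software.  The LI of a field is 100 × positive / (positive + negative).
The hot spot is the field with maximal LI among fields with at least
`min_nuclei` counted nuclei (default 500, configurable); the default
guards against a nearly empty field winning on a ratio of tiny counts,
and 500 nuclei bounds the binomial standard error of a 10% LI below
1.4 percentage points, comfortably inside the score-2 bin.  Ties are
broken by field identifier so repeated runs agree.  The patient-level
Ki-67 score is the three-level score of the hot-spot LI.

## Survival methodology

Metastasis-free survival (MFS) is time from resection/biopsy to distant
metastasis; patients without metastasis — including deaths without
documented metastasis — are censored at last follow-up.  MFS is the
stated endpoint, so death is censoring rather than a competing risk;
with metastasis-heavy event patterns this overstates net survival, a
known limitation accepted here.  Five years is taken as exactly 60.0
months.  Times must be positive: a metastasis recorded at time zero is
a staging finding, not a survival event, and is rejected.

`km_estimate()` is the product-limit estimator implemented from first
principles: S(t_i) = Π_{j≤i} (1 − d_j/n_j) over distinct event times,
with Greenwood variance S(t)² Σ d_j/(n_j(n_j − d_j)).  Conventions:

* **Ties.**  Events precede censorings at equal times: a subject
  censored at t is still at risk for the event at t.
* **Confidence band.**  95% pointwise, on the complementary log-log
  scale by default (limits S^exp(±z·se(log(−log S)))), which respects
  [0, 1]; the plain linear Greenwood band is available via `conf_type`.
  The software used for the original analyses does not document its
  transform, so the choice is ours; the log-log form is the common
  default in survival software and is what the test suite cross-checks
  against.
* **Degenerate values.**  The band is undefined where S is 0 or 1.
  When no event has occurred at or before the evaluation time,
  `survival_at()` returns S = 1 with the interval flagged undefined —
  the "no events until 5 years" footnote convention of clinical
  Table 1s, rather than a fabricated interval.

`logrank_test()` is the standard unweighted log-rank test: at each
pooled event time the observed minus hypergeometric-expected events per
group are accumulated along with the multivariate hypergeometric
covariance, and the statistic is the quadratic form over k − 1 groups
(reducing to (O − E)²/V for two groups), referred to the chi-square
upper tail on k − 1 degrees of freedom.  The covariance can be singular
when a group's risk set empties early, so the quadratic form uses a
Moore–Penrose inverse.  Three-group comparisons (low/intermediate/high)
are supported alongside the dichotomized two-group form.

## The synthetic cohort generator

No per-patient data are published for the 43-patient cohort the models
were evaluated on, so the generator emulates its *marginal* structure
and a two-group survival model; it makes the pipeline testable end to
end, it does not reconstruct any real patient.

* **Covariate marginals** default to the published per-variable counts
  (e.g. 24/43 aged ≥ 55, 24/10/3/6 across the size bins, 15/24/4 across
  the Ki-67 bins, 3/43 with necrosis ≥ 10%, 2/43 dedifferentiated).
  Variables are sampled independently: only marginals are known, and
  inventing a joint distribution would fabricate structure.  Real
  covariates are correlated (large tumors are more necrotic and more
  proliferative), so synthetic risk-category frequencies are *not*
  expected to match the published risk-model rows, which depend on the
  joint distribution.
* **Raw values** are uniform within the sampled score bin, recorded to
  one decimal and capped just below exclusive upper cut-offs so
  rounding never crosses a bin edge.  Open-ended bins are truncated at
  clinically plausible bounds: age 95 years, size 25 cm, mitoses
  10/mm², Ki-67 80%.
* **Follow-up** is log-normal with median 43 months and σ_log = 0.87
  (mean ≈ 63 months), clamped to 1–250 months — the reported follow-up
  summary of the motivating cohort.
* **Survival** depends on covariates only through the dichotomized risk
  group under a chosen model (default `modified3`): exponential
  metastasis times with `hazard_low` = 5 × 10⁻⁴ and `hazard_high` =
  5 × 10⁻³ per month.  The defaults give a low-risk stratum with
  essentially no events inside five years and an elevated stratum with
  roughly 74% five-year MFS (exp(−60 × 0.005) ≈ 0.74), the qualitative
  two-group structure the models are meant to separate.  Proportional
  exponential hazards are a deliberate simplification; richer
  covariate-survival dependence is out of scope.

Everything is driven by one integer seed; identical configurations
reproduce the cohort byte-for-byte in CSV form.

What passing tests on this generator do and do not show: they validate
the arithmetic, calibration and conventions of the pipeline under a
known truth; they cannot validate the clinical performance of the
models on real SFT cohorts, where covariates are correlated, hazards
are not exponential, and follow-up is informative.

## Validation design and problem sizes

The test suite validates the survival machinery along two independent
routes: hand-computed small cases and brute-force accumulations written
separately from the implementation, plus equivalence with the
`survival` package (estimates, Greenwood standard errors, log-log
confidence limits and log-rank statistics to 10⁻⁹) on 200 randomized
censored fixtures of up to 200 subjects with two or three groups.
Frequentist calibration uses sizes chosen to keep Monte-Carlo error
meaningful at desk scale: type-I error of the two-group log-rank test
over 5000 replicates of 50-per-group exponential null cohorts (accepted
within three Monte-Carlo standard errors of 0.05), and power over 500
replicates of 400-patient generated cohorts with a five-fold
dichotomized hazard ratio (base rate 0.002/month; rejection required in
at least 95%), with the ratio-1 control again within three Monte-Carlo
standard errors of 5%.  Marginal recovery of the generator is checked
by chi-square goodness of fit at n = 50,000.

## Reporting conventions

The Table-1-style report (`table1()`) lists, per variable block, the
level counts, their percentage of the cohort (rounded half away from
zero to one decimal — base R's round-half-even is not the convention of
clinical tables), five-year MFS with its 95% band, and the log-rank p
across the variable's levels.  A block with fewer than two populated
levels, or with no events at all, marks the p-value not computable
rather than printing a misleading number.  Displayed p-values use three
decimals floored at "<0.001": a printed "0.000" invites misreading as
exactly zero.  The machine-readable CSV keeps full precision; rounding
is display-only, so percentages always recompute exactly from counts.

## Known limitations

* Cut-offs are taken as published; no refitting, recalibration or Cox
  modelling is attempted, and no competing-risk treatment of death.
* The generator's independence and proportional-exponential assumptions
  understate the messiness of real cohorts (see above).
* The Ki-67 quantifier trusts upstream nucleus classification; field
  size and the original software's counting rules are not modeled.
* Published survival results for the motivating 43-patient cohort
  (five-year MFS values, log-rank p-values per stratum) depend on
  unpublished per-patient data and are therefore not reproducible
  quantities; the package reproduces the in-table arithmetic
  (percentages from counts) and validates the survival machinery
  against oracles instead.
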