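---
title: "New-user cohorts, cumulative insulin exposure and Poisson rate ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{New-user cohorts, cumulative insulin exposure and Poisson rate ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Whether long-acting insulin analogues (insulin glargine, insulin detemir)
modify cancer risk relative to human insulin is a question that observational
pharmacoepidemiology has repeatedly answered inconsistently, largely because
of design artefacts: prevalent-user bias, immortal time, time-lag bias, and
binary ever/never exposure definitions that ignore treatment duration.
`rxcohort` implements the design that addresses these artefacts end to end:

* a **new-user cohort** — only treatment initiators, identified by a one-year
  prescription-free lead-in, enter at their first insulin dispensing (the
  index date);
* an **active comparator** — human insulin, which shares the indication,
  rather than non-use;
* **time-varying cumulative exposure** — dispensed defined daily doses (DDDs)
  are converted to covered days at 1 DDD/day and accumulated per insulin
  class, so each person moves through duration categories as exposure
  accrues, and time before first use of a class is that class's non-exposed
  time (no immortal time);
* **semi-aggregated person-time** — events and person-years cross-classified
  by all categorical model covariates are sufficient statistics for the
  Poisson likelihood, allowing multi-country pooling without sharing
  person-level records;
* **Poisson rate models** — cell event counts with `log(person-years)` as
  offset, all three insulin exposures in one model, adjusted for
  time-dependent age and duration of insulin-treated diabetes, baseline
  calendar time, sex, country, and co-medication;
* **rate-ratio contrasts** — RR between two insulins at the same cumulative
  duration is `exp(beta_a - beta_b)` with a Wald CI from the coefficient
  covariance.

Because national registry records are confidential, the package pairs the
pipeline with a synthetic-registry generator whose true rate ratios are
known, making every stage testable.

## The pipeline

```{r}
library(rxcohort)
gen <- generate_bundle(effect_scenario(1.5), seed = 42)
asm <- assemble_cohort(gen$bundle)
iv  <- expand_cohort(asm$cohort, gen$bundle, scheme = "broad")
agg <- aggregate_person_time(iv, asm$cohort, endpoint = "any_cancer")
fit <- fit_poisson_rates(agg)
rr_table(fit, pairs = list(c("glargine", "human")))
```

### Cohort assembly

A person enters the cohort at the first-ever insulin dispensing if (a) that
dispensing falls at least 365 days after the start of observable registry
time, `max(data_start, study_start)` — persons entering observation
mid-study get their lead-in clock from the later of the two dates, since a
lead-in presumes observability; (b) age at index is at least 18 years; and
(c) there is no cancer history other than non-melanoma skin cancer (NMSC,
ICD-10 C44). Follow-up is half-open `[index, censor)` and ends at the first
of: any non-NMSC cancer, death, emigration/transfer out, end of the person's
data, or the country's study-period end. Exclusions are logged per criterion
so that included + excluded equals the distinct insulin users in the bundle.

Tie-breaks: a cancer recorded on the death date counts as a cancer censoring
(registries carry date resolution only, and cancer is the outcome of
interest). A cancer on the index date itself leaves zero follow-up and the
person is excluded. Multiple cancers on the censoring date are distinct
site-specific endpoints; a cancer at another site censors site-specific
follow-up without an event.

### Exposure engine

Each dispensing covers `ceiling(ddd_amount)` days at 1 DDD/day. A purchase
made while coverage remains extends coverage from the current coverage end
(stockpiling carry-forward) — the dispensed DDD total, not the dispensing
date pattern, determines total covered days. A purchase after a gap opens a
new episode; cumulative exposed time freezes during gaps and resumes on
re-exposure. Cumulative time counts covered days, not calendar days since
first use. Two configurable variants bracket alternative readings of
dispensing data: `stockpile = FALSE` discards leftover supply at each
refill instead of carrying it forward, and `grace_days > 0` bridges short
gaps between coverage end and the next purchase (approximating calendar
time while "on" treatment). The defaults — stockpiling, zero grace — treat
the dispensed DDD total as the authoritative count of covered days.

Follow-up is split on a 120-day grid; the exposure category of each insulin
class is evaluated at each interval start from the cumulative covered days
and frozen within the interval, even if a category boundary is crossed
mid-interval. Categories are half-open on the left, `(lo, hi]`, so exactly
half a year of exposure is still `<=0.5`; a person is exposed from the day
of the first dispensing (0 accumulated days at the index interval start maps
to `<=0.5`, not non-exposed). Two schemes are provided: `broad` (half-year
bins to 1 year, then 1-year bins, terminal `>6`) and `fine` (terminal
`9-10`). Years are days/365.25.

A brute-force day-by-day oracle (`day_level_oracle`) simulates the DDD stock
directly and is the independent reference for the interval engine; the two
are compared on a thousand randomized prescription histories in the tests.

### Covariates

Age enters as decade bands evaluated at the interval start; duration of
insulin-treated diabetes as whole years since index, capped at the exposure
scheme's terminal year so that small cohorts keep full rank; baseline
calendar time as 3-year bins of the index year (the bin width is
configurable; three years balances resolution against sparse strata at desk
scale). Baseline co-medication flags (NIAD A10B, statin C10A, NSAID M01A,
HRT G03) require at least one dispensing in the 365 days before index; HRT
is defined for women only. Diabetes type: age <= 30 with no NIAD on or
before index is type 1; age >= 40 is type 2; the rest unspecified.
Menopausal status is the age-50 cut-off evaluated per interval. Because
that proxy coincides exactly with the decade age-band boundary at 50, it is
linearly dependent on the age bands: the fitter detects the aliasing and
drops the redundant column with a warning, so the menopause sensitivity
variant runs and — necessarily, under this proxy — reproduces the
unadjusted results.

### Models and contrasts

`fit_poisson_rates` maximises the Poisson likelihood by iteratively
reweighted least squares on the semi-aggregate cells, with normal-equation
updates (`X'WX` via `crossprod`, Cholesky solve) — the tables are tall and
narrow, where this is an order of magnitude faster per iteration than a
weighted QR at an identical fixed point; the tests verify agreement with
`stats::glm` to 1e-8 on a dense table. Convergence is a relative deviance
change below 1e-12 with step-halving. Each insulin's exposure factor has its
own `non-exposed` reference level; contrasts between insulins at equal
duration are formed from coefficient differences with
`SE^2 = Var(a) + Var(b) - 2 Cov(a, b)` (Wald, not profile, intervals —
matching the normal-theory convention of the covariance-based contrast).
No multiple-testing correction is applied; the emitted table carries a
comparison count instead.

Sparse endpoints can lack a finite MLE (complete separation: some exposure
level with person-time but no events). Empty *levels* are dropped with a
warning; a diverging fit is a non-convergence error, and `run_main_analysis`
skips such endpoint-strata with a logged message rather than emitting
meaningless contrasts. The `other insulin` class timeline is computed but,
by default, omitted from the model; the three modelled exposures are human,
glargine, detemir.

Semi-aggregation is exactly likelihood-preserving: the Poisson likelihood
depends on the data only through events and person-years per covariate
pattern. Person-days are summed as integers and converted to years once, so
aggregated person-years equal summed follow-up to floating-point rounding
(tested at 1e-9 years), and collapsed and uncollapsed fits agree to 1e-8
over the identified coefficients (a separated level, having no finite MLE,
has no well-defined coefficient for the two routes to agree on).

## The synthetic registry

The generator emulates five country cohorts (DK, FI, NO, SE, UK) with the
study windows 1996–2010, 1996–2011, 2005–2010, 2007–2012 and 1987–2013, and
defaults fixed once to resemble the published baseline structure of a large
European insulin cohort:

* 20,000 persons split across countries in the published proportions
  (20/32/7/26/15%), 56% male, ages drawn from the published decade-band
  mixture (means around 60);
* prescribing as a semi-Markov refill chain: initiation probabilities
  0.55/0.25/0.12/0.08 for human/glargine/detemir/other, 90-DDD amounts every
  60–120 days, per-refill stop probability 0.04 (half of stops resume after
  180–720 days), switch probability 0.03, and a 30% chance of a concurrent
  second class — producing continuous coverage, gaps, switching and
  combination regimens;
* cancer hazards per site and sex totalling ~15.8/1000 person-years in men
  and ~13.0 in women, split across the ten studied sites plus a residual;
  death 30/1000 PY, emigration 2/1000 PY;
* deliberately ineligible fractions (5% insufficient lead-in, 2% under-age,
  3% cancer history, 1% NMSC history) so cohort exclusions are exercised.

The cancer hazard of each 120-day interval is the sex-specific baseline
multiplied by `exp` of the scenario's true log rate ratios of the person's
current duration category per insulin class, **evaluated on the same
120-day grid as the analysis**. Truth and estimand therefore coincide by
construction: recovery tests are exact parameter-recovery checks, not bias
studies of grid misclassification. What the generator does *not* emulate:
confounding (exposure assignment is independent of risk factors, so
adjusted and crude contrasts estimate the same quantity), dose variation
(fixed 1 DDD/day), country-specific prescribing culture, and secular trends.
Passing tests demonstrate the pipeline's statistical correctness under the
stated mechanism, not robustness to real-data confounding.

## Monte-Carlo design and problem sizes

`mc_effect_recovery` runs independent end-to-end replicates of
`effect_scenario(1.5)` (glargine RR 1.5 in every duration category) at
20,000 persons and pools the per-category glargine-vs-human log rate ratios
by inverse variance, propagating the full contrast covariance. With 200
replicates the mean pooled estimate lies within 3 Monte-Carlo standard
errors of `log 1.5` and the pooled Wald CI covers the truth at the nominal
95% level within binomial bounds.

`mc_null_calibration` runs the same pipeline under `null_scenario()` and
counts duration-category contrasts rejecting at 5%. The several contrasts
within one fitted model share reference coefficients and are correlated, so
calibration is judged with replicate-level (cluster) Monte-Carlo standard
errors rather than pooled binomial counts — the replicate, not the
contrast, is the independent unit.

The test suite runs both studies at 200 replicates; `scripts/acceptance.R`
reports the same quantities from 120 replicates, its own compromise between
Monte-Carlo error and a desk-scale runtime.

## Numerical choices and degenerate inputs

* Dates are ISO-8601 in files and integer day offsets internally.
* ICD prefix matching ignores dots (`C884` is `C88.4`); unmatched C-codes
  fall into `other_cancer`.
* The exact Poisson (Garwood) interval for a crude rate uses
  `chisq(0.025, 2x)` and `chisq(0.975, 2(x+1))` quantiles; zero events give
  a zero lower bound. Rates with 1–5 events are suppressed
  (count kept, rate withheld), mirroring registry confidentiality rules.
* Crude rates are reported per 1000 person-years.
* Identity contrasts (`RR(a, a)`) are exactly 1 with a degenerate CI;
  contrasting at the shared reference level is exactly null.
* Zero-length follow-up is excluded at assembly; an event attributed to a
  zero-length interval is a contract error in aggregation.
* `effect_scenario(rr)` requires `rr > 0`; an all-zero population is an
  error; identical `(scenario, seed)` give byte-identical CSV exports.

## Known limitations

* DDD-sum (dose) exposure metrics are out of scope; only duration is
  modelled.
* The CPRD-style derivation of DDDs from free-text dosage is not
  implemented; synthetic data supply DDD amounts directly.
* Wald intervals can be anticonservative in very sparse strata; the
  package skips non-identifiable fits rather than reporting them.
* The published five-country tables shipped with the package are
  aggregates; person-level replication of the published rate ratios is not
  possible from public data, which is precisely why the synthetic registry
  carries the burden of proof for the pipeline's correctness.
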