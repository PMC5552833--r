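#' Co-medication adjustment set for an endpoint
#'
#' Beyond NIAD use (always adjusted), liver and colorectal models adjust for
#' statin and NSAID use; breast and endometrial models additionally for HRT;
#' other endpoints carry no further co-medication terms.
#'
#' @param site Endpoint (cancer site or `"any_cancer"`).
#' @return Character vector of co-medication flag names (possibly empty).
#' @export
comed_set <- function(site) {
  switch(site,
         liver = , colorectal = c("statin", "nsaid"),
         breast = , endometrial = c("statin", "nsaid", "hrt"),
         character(0))
}

#' Collapse interval rows into a semi-aggregate event/person-year table
#'
#' Groups the 120-day interval rows by every categorical model covariate and
#' sums events and person-days per cell. Person-days are summed as integers
#' and converted to years once, so aggregated person-years equal summed
#' individual follow-up exactly. Cells with zero person-time cannot arise
#' (every interval has positive length). Because the Poisson likelihood
#' depends on the data only through events and person-years per covariate
#' pattern, models fitted on this table reproduce interval-level fits
#' exactly.
#'
#' @param intervals Interval table from [expand_cohort()].
#' @param cohort The cohort the intervals came from.
#' @param endpoint Cancer site or `"any_cancer"`.
#' @param sex_stratum `"male"`, `"female"` or `"both"`; sex-restricted
#'   endpoints (breast, endometrial, prostate) force their sex.
#' @param comed Co-medication flags to keep as strata
#'   (default [comed_set()] of the endpoint).
#' @param menopause Keep menopausal status as a stratum (women; default
#'   FALSE).
#' @param include_other Also stratify (and hence model) the `other insulin`
#'   exposure timeline (default FALSE: computed but omitted from models).
#' @return data.table of class `rx_semiagg`: one row per covariate pattern
#'   with `events` and `person_years`; attributes `endpoint`, `sex_stratum`
#'   and `keys`.
#' @export
aggregate_person_time <- function(intervals, cohort, endpoint = "any_cancer",
                                  sex_stratum = c("both", "male", "female"),
                                  comed = comed_set(endpoint),
                                  menopause = FALSE, include_other = FALSE) {
  sex_stratum <- match.arg(sex_stratum)
  forced <- endpoint_sex(endpoint)
  if (forced != "both") {
    if (sex_stratum == "both") sex_stratum <- forced
    if (sex_stratum != forced) {
      stop(endpoint, " is restricted to ", forced, " persons")
    }
  }
  ev <- endpoint_for_site(cohort, endpoint)
  ev_ids <- cohort$person_id[ev == 1L]

  keys <- c("country", if (sex_stratum == "both") "sex",
            "age_band", "calendar_band", "duration_band", "niad", comed,
            if (menopause) "menopausal_status",
            "exp_human", "exp_glargine", "exp_detemir",
            if (include_other) "exp_other_insulin")
  need <- c(keys, "sex", "person_id", "last_interval", "person_days")
  iv <- intervals[, unique(need), with = FALSE]
  if (sex_stratum != "both") iv <- iv[sex == sex_stratum]
  iv[, event := as.integer(last_interval & person_id %chin% ev_ids)]
  if (iv[, any(event == 1L & person_days <= 0)]) {
    stop("event attributed to an interval with zero person-time")
  }
  agg <- iv[, .(events = sum(event), person_days = sum(as.numeric(person_days))),
            by = keys]
  agg[, person_years := person_days / DAYS_PER_YEAR]
  agg[, person_days := NULL]
  data.table::setorderv(agg, keys)
  data.table::setattr(agg, "endpoint", endpoint)
  data.table::setattr(agg, "sex_stratum", sex_stratum)
  data.table::setattr(agg, "keys", keys)
  data.table::setattr(agg, "class", c("rx_semiagg", class(agg)))
  agg[]
}

#' Exact Poisson (Garwood) confidence interval for a rate
#'
#' For `x` events over `py` person-years the exact two-sided 95% interval
#' for the rate per 1000 person-years is
#' `1000 * chisq(0.025, 2x) / (2 py)` to
#' `1000 * chisq(0.975, 2(x+1)) / (2 py)` (lower bound 0 when `x = 0`).
#'
#' @param events Non-negative integer vector of event counts.
#' @param person_years Positive numeric vector of person-years.
#' @param level Confidence level (default 0.95).
#' @param per Rate multiplier (default 1000).
#' @return data.table with `rate`, `ci_lo`, `ci_hi` (per `per` person-years).
#' @export
#' @examples
#' crude_rate_ci(144, 184400)  # 0.78 (0.66, 0.92)
crude_rate_ci <- function(events, person_years, level = 0.95, per = 1000) {
  if (any(person_years <= 0)) stop("person_years must be positive")
  a <- (1 - level) / 2
  lo <- ifelse(events == 0, 0, stats::qchisq(a, 2 * events) / (2 * person_years))
  hi <- stats::qchisq(1 - a, 2 * (events + 1)) / (2 * person_years)
  data.table::data.table(rate = per * events / person_years,
                         ci_lo = per * lo, ci_hi = per * hi)
}

#' Crude incidence rates by country and sex with small-cell suppression
#'
#' Events are endpoint events ([endpoint_for_site()]); person-years are the
#' full follow-up of every cohort member of the stratum (all persons remain
#' at risk until censoring). Rates are per 1000 person-years with exact
#' Poisson confidence intervals. Cells with more than zero but fewer than
#' six events are suppressed: the count is kept, rate and interval are
#' withheld.
#'
#' @param cohort Cohort table from [assemble_cohort()].
#' @param endpoint Cancer site or `"any_cancer"`.
#' @param suppress_below Minimum publishable event count (default 6).
#' @return data.table with one row per country x sex: `events`,
#'   `person_years`, `rate`, `ci_lo`, `ci_hi`, `suppressed`.
#' @export
crude_rates <- function(cohort, endpoint = "any_cancer", suppress_below = 6L) {
  sexes <- switch(endpoint_sex(endpoint), both = c("male", "female"),
                  male = "male", female = "female")
  dt <- data.table::as.data.table(cohort)[sex %in% sexes]
  dt[, event := endpoint_for_site(dt, endpoint)]
  out <- dt[, .(events = sum(event),
                person_years = sum(follow_up_days) / DAYS_PER_YEAR),
            by = .(country, sex)]
  out <- cbind(out, crude_rate_ci(out$events, out$person_years))
  out[, suppressed := events > 0L & events < suppress_below]
  out[suppressed == TRUE, c("rate", "ci_lo", "ci_hi") := NA_real_]
  out[, endpoint := endpoint]
  data.table::setcolorder(out, c("endpoint", "country", "sex"))
  data.table::setorder(out, country, sex)
  out[]
}

#' Baseline and follow-up descriptive summary per country
#'
#' Cohort size, sex split, age at index (mean, SD, decade-band counts),
#' follow-up time (mean, SD, median, interquartile range), person-years
#' (total and in men), ever-use of each insulin class during follow-up, and
#' baseline co-medication counts.
#'
#' @param cohort Cohort table from [assemble_cohort()].
#' @param bundle The source `rx_bundle` (needed for ever-use of insulin
#'   classes during follow-up).
#' @return data.table with one row per country plus a `pooled` row.
#' @export
cohort_descriptives <- function(cohort, bundle) {
  dt <- data.table::as.data.table(cohort)
  rx <- bundle$prescriptions[dt[, .(person_id, index_date, censor_date)],
                             on = "person_id", nomatch = NULL]
  rx[, cls := classify_insulin(atc_code, bundle$dictionary)]
  ever <- rx[cls != "non_insulin" & dispense_date >= index_date &
             dispense_date < censor_date,
             .(person_id = unique(person_id)), by = cls]
  ever <- dt[, .(person_id, country)][ever, on = "person_id"]

  one <- function(sub, ev_sub, label) {
    fu <- sub$follow_up_days / DAYS_PER_YEAR
    row <- data.table::data.table(
      country = label, n = nrow(sub),
      n_male = sub[, sum(sex == "male")],
      pct_male = 100 * sub[, mean(sex == "male")],
      age_mean = mean(sub$age_at_index), age_sd = sd(sub$age_at_index),
      fu_mean = mean(fu), fu_sd = sd(fu),
      fu_median = stats::median(fu),
      fu_q1 = unname(stats::quantile(fu, 0.25)),
      fu_q3 = unname(stats::quantile(fu, 0.75)),
      person_years = sum(fu),
      person_years_male = sub[sex == "male", sum(follow_up_days)] / DAYS_PER_YEAR)
    for (cl in insulin_classes()) {
      row[, (paste0("ever_", cl)) := ev_sub[cls == cl, data.table::uniqueN(person_id)]]
    }
    for (fl in c("niad", "statin", "nsaid", "hrt")) {
      row[, (paste0("baseline_", fl)) := sum(sub[[fl]])]
    }
    bands <- table(age_band(sub$age_at_index))
    for (b in names(bands)) row[, (paste0("age_", b)) := as.integer(bands[[b]])]
    row
  }
  rows <- lapply(sort(unique(dt$country)), function(co) {
    one(dt[country == co], ever[country == co], co)
  })
  rows <- c(rows, list(one(dt, ever, "pooled")))
  data.table::rbindlist(rows, fill = TRUE)
}

#' @export
print.rx_semiagg <- function(x, ...) {
  cat(sprintf("<rx_semiagg> endpoint=%s sex=%s cells=%d events=%d PY=%.1f\n",
              attr(x, "endpoint"), attr(x, "sex_stratum"), nrow(x),
              sum(x$events), sum(x$person_years)))
  invisible(x)
}
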