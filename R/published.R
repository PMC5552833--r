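#' Published five-country cohort summary tables
#'
#' The package ships, as plain-text reference data, the aggregate baseline
#' and outcome summaries of a published five-country new-insulin-user cohort
#' (Denmark, Finland, Norway, Sweden and the UK CPRD; 327,112 persons):
#' per-country cohort size, sex split, mean follow-up, person-years,
#' ever-use of each insulin class, and sex- and site-specific cancer case
#' counts. Only aggregates are shipped — the underlying registry records are
#' confidential. These tables exercise the pooling and crude-rate machinery
#' on real published magnitudes; cells originally suppressed for
#' confidentiality (fewer than six events) are `NA`.
#'
#' @return `published_summary()`: list with `cohorts` (one row per country)
#'   and `cancer_counts` (one row per endpoint x sex, one column per
#'   country).
#' @export
#' @examples
#' s <- published_summary()
#' sum(s$cohorts$n)
published_summary <- function() {
  dir <- system.file("extdata", package = "rxcohort")
  list(
    cohorts = data.table::fread(file.path(dir, "fivecountry_summary.csv")),
    cancer_counts = data.table::fread(file.path(dir,
                                                "fivecountry_cancer_counts.csv"))
  )
}

#' Pool per-country published summaries
#'
#' Reduces the per-country summary to the pooled quantities: total cohort
#' size, total person-years, the cohort-size-weighted mean follow-up, total
#' cancer cases and pooled ever-use counts per insulin class.
#'
#' @param summary Output of [published_summary()] (or a list of the same
#'   shape).
#' @return Named list of pooled values (`person_years` in absolute years).
#' @export
#' @examples
#' pooled_published(published_summary())$n
pooled_published <- function(summary = published_summary()) {
  co <- summary$cohorts
  cc <- summary$cancer_counts
  country_cols <- intersect(co$country, names(cc))
  counts <- as.matrix(cc[, country_cols, with = FALSE])
  list(
    n = sum(co$n),
    person_years = 1000 * sum(co$py_thousand),
    person_years_male = 1000 * sum(co$py_male_thousand),
    mean_follow_up = sum(co$n * co$mean_fu_years) / sum(co$n),
    cancer_cases = sum(counts[cc$endpoint == "any_cancer", ], na.rm = TRUE),
    ever_use = c(
      human = sum(co$ever_human), glargine = sum(co$ever_glargine),
      detemir = sum(co$ever_detemir),
      other_insulin = sum(co$ever_other_insulin))
  )
}
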