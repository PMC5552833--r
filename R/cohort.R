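#' Assemble the new-user insulin cohort
#'
#' Identifies every insulin user in the bundle (first-ever dispensing of any
#' insulin = index date) and applies the inclusion criteria of a new-user
#' design, in order:
#'
#' 1. lead-in: the index date falls at least `leadin_days` after the start of
#'    observable registry time, `max(data_start, study_start)`;
#' 2. age at index at least `min_age` years;
#' 3. no history of cancer (except non-melanoma skin cancer) strictly before
#'    the index date;
#' 4. positive follow-up (`index_date < censor_date`).
#'
#' Follow-up runs from the index date to the earliest of first non-NMSC
#' cancer, death, emigration/transfer out, end of the person's data, and the
#' country's study-period end. On same-day ties cancer takes precedence over
#' death, death over emigration. Person-time is half-open
#' `[index_date, censor_date)` with the event attributed to the final day.
#'
#' @param bundle A validated `rx_bundle`.
#' @param leadin_days Lead-in length in days (default 365).
#' @param min_age Minimum age at index in years (default 18).
#' @return List with `cohort` (one row per included person: index and censor
#'   dates, censor reason, age at index, diabetes type, baseline
#'   co-medication flags, first cancer site(s)) and `exclusions` (one row
#'   per excluded insulin user with the first failed criterion).
#' @export
assemble_cohort <- function(bundle, leadin_days = 365L, min_age = 18) {
  dict <- bundle$dictionary
  rx <- bundle$prescriptions
  rx_ins <- rx[classify_insulin(atc_code, dict) != "non_insulin"]
  if (!nrow(rx_ins)) {
    return(list(cohort = data.table::data.table(),
                exclusions = data.table::data.table(person_id = character(),
                                                    reason = character())))
  }
  base <- rx_ins[, .(index_date = min(dispense_date)), by = person_id]
  base <- bundle$persons[base, on = "person_id"]
  base <- bundle$study_period[base, on = "country"]
  base[, obs_start := pmax(data_start, study_start)]
  base[, age_at_index := as.numeric(index_date - birth_date) / DAYS_PER_YEAR]

  ev <- data.table::copy(bundle$events)
  ev[, site := NA_character_]
  ev[event_type == "cancer", site := classify_cancer_site(diagnosis_code, dict)]
  ca <- ev[event_type == "cancer" & site != "nmsc"]

  # (suppressWarnings: data.table probes j on an empty prototype, which
  # makes min() over zero dates warn spuriously)
  prior <- ca[base, on = "person_id", nomatch = NULL][event_date < index_date,
               .(prior_cancer = TRUE), by = person_id]
  first_ca <- ca[base, on = "person_id", nomatch = NULL][event_date >= index_date]
  first_ca <- suppressWarnings(
    first_ca[, .(cancer_date = min(event_date)), by = person_id])[
    first_ca, on = "person_id", nomatch = NULL][event_date == cancer_date,
    .(cancer_date = cancer_date[1L],
      first_cancer_sites = paste(sort(unique(site)), collapse = ";")),
    by = person_id]
  deaths <- suppressWarnings(
    ev[event_type == "death", .(death_date = min(event_date)), by = person_id])
  emig <- suppressWarnings(
    ev[event_type == "emigration", .(emig_date = min(event_date)),
       by = person_id])

  base <- first_ca[base, on = "person_id"]
  base <- deaths[base, on = "person_id"]
  base <- emig[base, on = "person_id"]
  base <- prior[base, on = "person_id"]
  base[is.na(prior_cancer), prior_cancer := FALSE]

  admin_end <- base[, pmin(data_end, study_end)]
  cand <- cbind(as.numeric(base$cancer_date), as.numeric(base$death_date),
                as.numeric(base$emig_date), as.numeric(admin_end))
  cand[is.na(cand)] <- Inf
  censor_num <- pmin(cand[, 1L], cand[, 2L], cand[, 3L], cand[, 4L])
  # tie precedence: cancer > death > emigration/transfer > administrative end
  reasons <- c("cancer", "death", "emigration_or_transfer", "admin_end")
  which_reason <- max.col(cand == censor_num, ties.method = "first")
  base[, censor_date := as.Date(censor_num, origin = "1970-01-01")]
  base[, censor_reason := reasons[which_reason]]
  base[censor_reason != "cancer", first_cancer_sites := ""]
  base[is.na(first_cancer_sites), first_cancer_sites := ""]

  base[, reason := data.table::fcase(
    index_date < obs_start + leadin_days, "insufficient_leadin",
    age_at_index < min_age, "age_lt_18",
    prior_cancer == TRUE, "prior_cancer",
    censor_date <= index_date, "zero_followup",
    default = "included")]

  exclusions <- base[reason != "included", .(person_id, reason)]
  cohort <- base[reason == "included"]

  # baseline covariates from the co-medication dictionary
  com <- rx[cohort[, .(person_id, index_date)], on = "person_id", nomatch = NULL]
  com[, cls := classify_comed(atc_code, dict)]
  com <- com[!is.na(cls)]
  niad_ever <- com[cls == "niad" & dispense_date <= index_date,
                   unique(person_id)]
  in_window <- com[dispense_date >= index_date - DAYS_PER_YEAR_INT &
                   dispense_date < index_date]
  for (fl in c("niad", "statin", "nsaid", "hrt")) {
    ids <- in_window[cls == fl, unique(person_id)]
    cohort[, (fl) := person_id %in% ids]
  }
  cohort[sex == "male", hrt := FALSE]
  cohort[, diabetes_type := classify_diabetes(age_at_index,
                                              person_id %in% niad_ever)]

  cohort <- cohort[, .(person_id, sex, country, birth_date, index_date,
                       censor_date, censor_reason, age_at_index,
                       diabetes_type, niad, statin, nsaid, hrt,
                       first_cancer_sites,
                       follow_up_days = as.integer(censor_date - index_date))]
  data.table::setorder(cohort, person_id)
  list(cohort = cohort, exclusions = exclusions)
}

DAYS_PER_YEAR_INT <- 365L

#' Classify diabetes type from age and baseline NIAD use
#'
#' Type 1 is assigned to persons aged 30 or under at index with no
#' non-insulin antidiabetic drug (NIAD) on or before the index date; type 2
#' to those aged 40 or over (with or without NIADs); the rest are
#' `unspecified`.
#'
#' @param age_at_index Numeric vector, age in years at the index date.
#' @param niad_at_index Logical vector: any NIAD dispensing on or before
#'   the index date.
#' @return Factor with levels `type1`, `type2`, `unspecified`.
#' @export
#' @examples
#' classify_diabetes(c(25, 62, 35), c(FALSE, TRUE, FALSE))
classify_diabetes <- function(age_at_index, niad_at_index) {
  out <- data.table::fcase(
    age_at_index <= 30 & !niad_at_index, "type1",
    age_at_index >= 40, "type2",
    default = "unspecified")
  factor(out, levels = c("type1", "type2", "unspecified"))
}

#' Sex restriction of an endpoint
#'
#' Breast and endometrial cancer are analysed in women only, prostate in men
#' only; all other endpoints in both sexes.
#'
#' @param site A cancer site or `"any_cancer"`.
#' @return `"male"`, `"female"` or `"both"`.
#' @export
endpoint_sex <- function(site) {
  stopifnot(site %in% c(cancer_sites(), "any_cancer"))
  if (site %in% c("breast", "endometrial")) return("female")
  if (site == "prostate") return("male")
  "both"
}

#' Endpoint indicator for a cancer site
#'
#' A person is an event for a site-specific endpoint if follow-up ended in
#' cancer and the site is among the cancers diagnosed on the censoring date
#' (multiple same-day cancers count as distinct site-specific endpoints).
#' For the `any_cancer` endpoint every cancer censoring is an event. Cancer
#' at another site censors without an event.
#'
#' @param cohort Cohort table from [assemble_cohort()].
#' @param site A cancer site from [cancer_sites()] (not `nmsc`), or
#'   `"any_cancer"`.
#' @return Integer vector of 0/1 event indicators aligned with `cohort` rows.
#' @export
endpoint_for_site <- function(cohort, site) {
  if (!site %in% c(setdiff(cancer_sites(), "nmsc"), "any_cancer")) {
    stop("unknown endpoint site: ", site)
  }
  is_cancer <- cohort$censor_reason == "cancer"
  if (site == "any_cancer") return(as.integer(is_cancer))
  hit <- vapply(strsplit(cohort$first_cancer_sites, ";", fixed = TRUE),
                function(s) site %in% s, logical(1))
  as.integer(is_cancer & hit)
}
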