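#' Coverage episodes for one person and drug class
#'
#' Converts dispensing records of one person and one drug class into
#' half-open coverage episodes `[start, end)` in days, assuming consumption
#' of 1 DDD per day. Each record covers `ceiling(ddd_amount)` days; a
#' purchase arriving while coverage remains extends coverage from the current
#' coverage end (stockpiling carry-forward); a purchase after a gap starts a
#' new episode at its dispense day. Abutting episodes are merged and episodes
#' are truncated at `follow_up_end`.
#'
#' @param dispense_day Integer vector of dispense days (offsets from the
#'   index date), sorted non-decreasingly.
#' @param ddd_amount Positive numeric vector of dispensed DDD amounts.
#' @param follow_up_end Day offset at which follow-up ends (episodes are
#'   truncated here); `Inf` for no truncation.
#' @param stockpile Carry remaining supply forward when a purchase arrives
#'   while coverage remains (default TRUE); FALSE discards leftover supply
#'   and restarts coverage at the purchase.
#' @param grace_days Bridge gaps of up to this many days between the
#'   coverage end and the next purchase (the bridged days count as covered;
#'   default 0).
#' @return data.table with columns `start`, `end` (half-open day offsets).
#' @export
#' @examples
#' coverage_episodes(c(0, 30), c(50, 50), 400)   # one episode [0, 100)
#' coverage_episodes(c(0, 60), c(30, 30), 400)   # [0, 30) and [60, 90)
coverage_episodes <- function(dispense_day, ddd_amount, follow_up_end = Inf,
                              stockpile = TRUE, grace_days = 0L) {
  stopifnot(length(dispense_day) == length(ddd_amount),
            all(is.finite(ddd_amount)), all(ddd_amount > 0), grace_days >= 0)
  if (is.unsorted(dispense_day)) {
    stop("dispense_day must be sorted non-decreasingly")
  }
  if (!length(dispense_day)) {
    return(data.table::data.table(start = integer(), end = integer()))
  }
  ep <- build_coverage_episodes(rep(1L, length(dispense_day)),
                                as.integer(dispense_day),
                                as.integer(ceiling(ddd_amount)),
                                stockpile, as.integer(grace_days))
  ep <- data.table::as.data.table(ep)
  ep <- ep[ep_start < follow_up_end]
  if (is.finite(follow_up_end)) {
    ep[, ep_end := pmin(ep_end, as.integer(follow_up_end))]
  }
  ep[, .(start = ep_start, end = ep_end)]
}

#' Cumulative exposed days at a time point
#'
#' Sum over episodes of the overlap with `[0, t)`: zero before the first
#' episode, frozen during gaps, resuming on re-exposure.
#'
#' @param t Numeric vector of day offsets (`>= 0`).
#' @param episodes data.table from [coverage_episodes()].
#' @return Numeric vector of cumulative exposed days at each `t`.
#' @export
#' @examples
#' ep <- coverage_episodes(c(0, 60), c(30, 30))
#' cumulative_days_at(c(0, 75, 500), ep)  # 0, 45, 60
cumulative_days_at <- function(t, episodes) {
  stopifnot(all(t >= 0))
  vapply(t, function(tt) {
    sum(pmax(0, pmin(tt, episodes$end) - episodes$start))
  }, numeric(1))
}

#' Day-resolution exposure oracle
#'
#' Brute-force day-by-day simulation of the DDD stock: each dispensing adds
#' `ceiling(ddd_amount)` days of supply, each covered day consumes one. Used
#' as an independent reference for the interval engine in tests; quadratic in
#' follow-up length, intended for small inputs only.
#'
#' @param prescriptions data.frame with columns `day` (offset from index),
#'   `class` (drug class label) and `ddd_amount`.
#' @param follow_up_end Number of follow-up days to simulate.
#' @return data.table with one row per class and day `0 .. follow_up_end-1`:
#'   `covered` (was the day exposed), `cum_days_start` (cumulative exposed
#'   days before this day) and `ever` (any dispensing on or before this day).
#' @export
day_level_oracle <- function(prescriptions, follow_up_end) {
  stopifnot(follow_up_end >= 1)
  rx <- data.table::as.data.table(prescriptions)
  out <- lapply(unique(rx$class), function(cl) {
    sub <- rx[class == cl]
    adds <- integer(follow_up_end)
    in_range <- sub$day >= 0 & sub$day < follow_up_end
    for (i in which(in_range)) {
      adds[sub$day[i] + 1L] <- adds[sub$day[i] + 1L] +
        as.integer(ceiling(sub$ddd_amount[i]))
    }
    stock <- 0L; cum <- 0L
    covered <- logical(follow_up_end)
    cum_start <- integer(follow_up_end)
    for (d in seq_len(follow_up_end)) {
      stock <- stock + adds[d]
      cum_start[d] <- cum
      if (stock > 0L) {
        covered[d] <- TRUE
        stock <- stock - 1L
        cum <- cum + 1L
      }
    }
    data.table::data.table(class = cl, day = 0:(follow_up_end - 1L),
                           covered = covered, cum_days_start = cum_start,
                           ever = (0:(follow_up_end - 1L)) >= min(sub$day))
  })
  data.table::rbindlist(out)
}

# ---- vectorised internals -------------------------------------------------

# Episodes for every person x insulin class in one pass.
# `index` is a data.table(person_id, index_date); prescriptions before the
# index or outside the insulin group are dropped. Episodes are NOT truncated
# (queries clamp at follow-up themselves).
insulin_episode_table <- function(prescriptions, index, dictionary,
                                  stockpile = TRUE, grace_days = 0L) {
  rx <- prescriptions[index, on = "person_id", nomatch = NULL]
  rx[, cls := classify_insulin(atc_code, dictionary)]
  rx <- rx[cls != "non_insulin"]
  rx[, offset_day := as.integer(dispense_date - index_date)]
  rx <- rx[offset_day >= 0L]
  if (!nrow(rx)) {
    return(data.table::data.table(person_id = character(), cls = character(),
                                  ep_start = integer(), ep_end = integer(),
                                  cum_before = numeric()))
  }
  rx[, pid := match(person_id, index$person_id)]
  rx[, class_id := match(cls, insulin_classes())]
  rx[, group := (pid - 1L) * 4L + class_id]
  data.table::setorder(rx, group, offset_day)
  ep <- data.table::as.data.table(build_coverage_episodes(
    rx$group, rx$offset_day, as.integer(ceiling(rx$ddd_amount)),
    stockpile, as.integer(grace_days)))
  ep[, pid := (group - 1L) %/% 4L + 1L]
  ep[, class_id := (group - 1L) %% 4L + 1L]
  ep[, person_id := index$person_id[pid]]
  ep[, cls := insulin_classes()[class_id]]
  ep[, .(person_id, cls, ep_start, ep_end, cum_before)]
}

# Cumulative exposed days and ever-exposed flags at query times, for one
# class, via a rolling join to the last episode starting at or before t.
grid_cum_days <- function(episodes, queries, class) {
  ep <- episodes[cls == class,
                 .(person_id, ep_s = ep_start, ep_end, cum_before,
                   ep_start = ep_start)]
  if (!nrow(ep)) {
    return(list(cum = numeric(nrow(queries)), ever = rep(FALSE, nrow(queries))))
  }
  res <- ep[queries, on = c("person_id", "ep_start" = "t_query"), roll = Inf]
  cum <- res$cum_before + pmin(res$ep_start - res$ep_s, res$ep_end - res$ep_s)
  ever <- !is.na(res$ep_s)
  cum[!ever] <- 0
  list(cum = cum, ever = ever)
}

#' Expand a cohort into 120-day interval rows
#'
#' Splits each person's follow-up `[0, censor - index)` into a grid of
#' 120-day intervals (the last interval truncated at censoring) and evaluates
#' the time-varying covariates at each interval start: cumulative exposed
#' days and the duration category per insulin class, decade age band,
#' duration of insulin-treated diabetes (1-year bands, capped at the
#' scheme's terminal year), baseline calendar band and menopausal status
#' (post if a woman is 50 or older at the interval start). Exposure state is
#' frozen within each interval.
#'
#' @param cohort Cohort table from [assemble_cohort()] (or a subset of it).
#' @param bundle The `rx_bundle` the cohort was assembled from.
#' @param scheme Category scheme name or object (see [category_scheme()]).
#' @param grid_days Interval width in days (default 120).
#' @param episodes Optional precomputed coverage-episode table (as stored in
#'   an `rx_truth`); recomputed from the bundle's prescriptions when NULL.
#' @param stockpile,grace_days Coverage options (see [coverage_episodes()]),
#'   used only when episodes are recomputed.
#' @return data.table of interval rows, one per person x interval, with
#'   exposure factors `exp_human`, `exp_glargine`, `exp_detemir`,
#'   `exp_other_insulin`, covariate bands, `person_days` and a
#'   `last_interval` flag. `attr(,"scheme")` records the scheme name.
#' @export
expand_cohort <- function(cohort, bundle, scheme = "broad", grid_days = 120L,
                          episodes = NULL, stockpile = TRUE, grace_days = 0L) {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  cohort <- data.table::as.data.table(cohort)
  fu <- as.integer(cohort$censor_date - cohort$index_date)
  if (any(fu <= 0)) stop("censor_date must be after index_date for all records")

  n_int <- as.integer(ceiling(fu / grid_days))
  pid <- rep(seq_len(nrow(cohort)), n_int)
  k <- sequence(n_int) - 1L
  start <- k * grid_days
  end <- pmin(start + grid_days, fu[pid])

  iv <- data.table::data.table(
    person_id = cohort$person_id[pid],
    interval_start = start,
    interval_end = end,
    person_days = end - start,
    last_interval = (k == n_int[pid] - 1L)
  )

  ep <- if (is.null(episodes)) {
    insulin_episode_table(bundle$prescriptions, cohort[, .(person_id, index_date)],
                          bundle$dictionary, stockpile, grace_days)
  } else episodes
  queries <- iv[, .(person_id, t_query = interval_start)]
  for (cl in insulin_classes()) {
    g <- grid_cum_days(ep, queries, cl)
    iv[, (paste0("cum_", cl)) := g$cum]
    iv[, (paste0("exp_", cl)) := categorize_exposure(g$cum, scheme, g$ever)]
  }
  age_at_index <- as.numeric(cohort$index_date - cohort$birth_date) / DAYS_PER_YEAR
  age_iv <- age_at_index[pid] + start / DAYS_PER_YEAR
  iv[, age_band := age_band(age_iv)]
  iv[, duration_band := duration_band(interval_start, scheme)]
  cal <- droplevels(calendar_band(cohort$index_date))
  iv[, calendar_band := cal[pid]]
  sex_f <- factor(cohort$sex, levels = c("male", "female"))
  country_f <- factor(cohort$country, levels = countries())
  iv[, sex := sex_f[pid]]
  iv[, country := country_f[pid]]
  men_idx <- data.table::fifelse(sex_f[pid] == "male", 1L,
                                 data.table::fifelse(age_iv >= 50, 3L, 2L))
  iv[, menopausal_status := structure(men_idx, levels = c("n/a", "pre", "post"),
                                      class = "factor")]
  for (fl in c("niad", "statin", "nsaid", "hrt")) {
    if (fl %in% names(cohort)) iv[, (fl) := cohort[[fl]][pid]]
  }
  if ("diabetes_type" %in% names(cohort)) {
    iv[, diabetes_type := cohort$diabetes_type[pid]]
  }
  data.table::setattr(iv, "scheme", scheme$name)
  iv[]
}
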