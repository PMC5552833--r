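#' Simulation scenarios for the synthetic registry
#'
#' A scenario fixes every knob of the synthetic five-country registry:
#' cohort sizes, the study window per country, the baseline age/sex mixture,
#' the prescribing process (initiation probabilities per insulin class,
#' refill gaps, DDD amount per refill, per-refill stop/switch probabilities),
#' cancer hazards per site and sex, the true log rate ratios per insulin
#' class and broad cumulative-duration category, censoring hazards for death
#' and emigration, baseline co-medication probabilities, and the fractions
#' of deliberately ineligible persons (insufficient lead-in, under-age,
#' cancer history) that exercise the cohort exclusions.
#'
#' `null_scenario()` sets every true log rate ratio to zero;
#' `effect_scenario(rr)` gives insulin glargine a constant rate ratio `rr`
#' versus human insulin in every duration category. Defaults are sized for
#' desk-scale runs (20,000 persons split across the five countries in
#' realistic proportions).
#'
#' @param n_total Total number of persons across the five countries.
#' @param seed Default RNG seed stored in the scenario.
#' @return An `rx_scenario` list; see Details for the fields.
#' @export
#' @examples
#' sc <- null_scenario(n_total = 500)
#' sapply(sc$true_log_rr, sum)
null_scenario <- function(n_total = 20000L, seed = 1L) {
  props <- c(DK = 0.204, FI = 0.324, NO = 0.066, SE = 0.261, UK = 0.145)
  n <- round(n_total * props / sum(props))
  labels <- category_scheme("broad")$labels
  zero <- stats::setNames(rep(0, length(labels)), labels)
  sc <- list(
    n_per_country = n,
    study_period = data.table::data.table(
      country = c("DK", "FI", "NO", "SE", "UK"),
      study_start = as.Date(c("1996-01-01", "1996-01-01", "2005-01-01",
                              "2007-01-01", "1987-01-01")),
      study_end = as.Date(c("2010-12-31", "2011-12-31", "2010-12-31",
                            "2012-12-31", "2013-12-31"))),
    age_bands = data.table::data.table(
      lo = c(18, 30, 40, 50, 60, 70, 80),
      hi = c(30, 40, 50, 60, 70, 80, 95),
      prob = c(0.046, 0.075, 0.112, 0.201, 0.241, 0.197, 0.128)),
    sex_ratio_male = 0.56,
    prescribing = list(
      init_probs = c(human = 0.55, glargine = 0.25, detemir = 0.12,
                     other_insulin = 0.08),
      second_class_prob = 0.30,
      refill_gap = c(60L, 120L),
      ddd_per_refill = 90,
      stop_prob = 0.04,
      switch_prob = 0.03,
      resume_prob = 0.5,
      resume_gap = c(180L, 720L),
      max_refills = 200L),
    # events per 1000 person-years; site split follows the incidence pattern
    # of an elderly insulin-treated population (totals ~15.8 men, ~13.0 women)
    baseline_hazards = data.table::data.table(
      site = c("liver", "pancreas", "lung", "melanoma", "bladder",
               "colorectal", "nhl", "breast", "endometrial", "prostate",
               "other_cancer"),
      men = c(0.78, 1.60, 1.93, 0.45, 0.91, 1.87, 0.43, 0, 0, 3.49, 4.38),
      women = c(0.27, 1.54, 1.02, 0.33, 0.27, 1.38, 0.40, 2.70, 0.96, 0,
                4.11)),
    true_log_rr = list(human = zero, glargine = zero, detemir = zero),
    censoring_hazards = c(death = 30, emigration = 2),
    comed_probs = c(niad = 0.75, statin = 0.40, nsaid = 0.25, hrt = 0.15),
    ineligible = c(short_leadin = 0.05, underage = 0.02, prior_cancer = 0.03),
    nmsc_history_prob = 0.01,
    seed = as.integer(seed)
  )
  structure(sc, class = "rx_scenario")
}

#' @rdname null_scenario
#' @param rr Constant glargine-vs-human rate ratio (`> 0`) applied in every
#'   duration category.
#' @export
effect_scenario <- function(rr, n_total = 20000L, seed = 1L) {
  if (!is.numeric(rr) || length(rr) != 1L || !is.finite(rr) || rr <= 0) {
    stop("rr must be a single positive number")
  }
  sc <- null_scenario(n_total = n_total, seed = seed)
  sc$true_log_rr$glargine[] <- log(rr)
  sc
}

#' Read or write a simulation scenario as JSON
#'
#' Serialises every scenario field (dates as ISO-8601 strings) so that a
#' scenario can be version-controlled and passed to [run_pipeline()].
#'
#' @param scenario An `rx_scenario`.
#' @param path Path to a JSON file.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns a validated `rx_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  validate_scenario(scenario)
  x <- unclass(scenario)
  x$study_period <- data.table::copy(x$study_period)
  x$study_period[, study_start := format(study_start, "%Y-%m-%d")]
  x$study_period[, study_end := format(study_end, "%Y-%m-%d")]
  # named atomic vectors must become objects, not nameless arrays
  as_obj <- function(v) as.list(v)
  x$n_per_country <- as_obj(x$n_per_country)
  x$prescribing <- lapply(x$prescribing, as_obj)
  x$true_log_rr <- lapply(x$true_log_rr, as_obj)
  x$censoring_hazards <- as_obj(x$censoring_hazards)
  x$comed_probs <- as_obj(x$comed_probs)
  x$ineligible <- as_obj(x$ineligible)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- null_scenario()
  for (nm in names(sc)) {
    if (!nm %in% names(x)) stop("scenario file lacks field: ", nm)
  }
  sc <- structure(x[names(sc)], class = "rx_scenario")
  sc$n_per_country <- unlist(sc$n_per_country)
  sc$study_period <- data.table::as.data.table(sc$study_period)
  sc$study_period[, study_start := as.Date(study_start)]
  sc$study_period[, study_end := as.Date(study_end)]
  sc$age_bands <- data.table::as.data.table(sc$age_bands)
  sc$baseline_hazards <- data.table::as.data.table(sc$baseline_hazards)
  sc$prescribing <- lapply(sc$prescribing, unlist)
  sc$true_log_rr <- lapply(sc$true_log_rr, unlist)
  sc$censoring_hazards <- unlist(sc$censoring_hazards)
  sc$comed_probs <- unlist(sc$comed_probs)
  sc$ineligible <- unlist(sc$ineligible)
  sc$seed <- as.integer(sc$seed)
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "rx_scenario"))
  if (any(sc$baseline_hazards$men < 0) || any(sc$baseline_hazards$women < 0) ||
      any(sc$censoring_hazards < 0)) {
    stop("scenario hazards must be non-negative")
  }
  probs <- c(sc$prescribing$init_probs, sc$prescribing$stop_prob,
             sc$prescribing$switch_prob, sc$prescribing$resume_prob,
             sc$prescribing$second_class_prob, sc$comed_probs,
             sc$ineligible, sc$nmsc_history_prob, sc$sex_ratio_male,
             sc$age_bands$prob)
  if (any(probs < 0 | probs > 1)) stop("scenario probabilities must be in [0, 1]")
  labels <- category_scheme("broad")$labels
  for (cl in c("human", "glargine", "detemir")) {
    if (!all(labels %in% names(sc$true_log_rr[[cl]]))) {
      stop("true_log_rr$", cl, " must cover every broad duration category")
    }
  }
  invisible(sc)
}

site_icd10 <- function(site) {
  codes <- c(liver = "C22", pancreas = "C25", lung = "C34", melanoma = "C43",
             bladder = "C67", colorectal = "C18", nhl = "C83", breast = "C50",
             endometrial = "C54", prostate = "C61", nmsc = "C44",
             other_cancer = "C71")
  unname(codes[site])
}

# Refill chains for all persons at once. One row per dispensing:
# (pid, day offset from index, class). Chains evolve refill by refill with
# i.i.d. gaps; stopping may be permanent or followed by a late resumption;
# switching moves the chain to another class.
simulate_prescribing <- function(n, admin_days, pr) {
  cls_names <- names(pr$init_probs)
  multi_class <- sum(pr$init_probs > 0) > 1L   # switching needs an alternative
  draw_class <- function(m) {
    cls_names[sample.int(length(cls_names), m, replace = TRUE,
                         prob = pr$init_probs)]
  }
  pid <- seq_len(n)
  chain_pid <- pid
  chain_cls <- draw_class(n)
  second <- if (multi_class) {
    which(stats::runif(n) < pr$second_class_prob)
  } else integer(0)
  if (length(second)) {
    cls2 <- draw_class(length(second))
    # a concurrent second class must differ from the first
    clash <- cls2 == chain_cls[second]
    while (any(clash)) {
      cls2[clash] <- draw_class(sum(clash))
      clash <- cls2 == chain_cls[second]
    }
    chain_pid <- c(chain_pid, second)
    chain_cls <- c(chain_cls, cls2)
  }
  day <- c(rep(0L, n),
           if (length(second)) sample.int(91L, length(second),
                                          replace = TRUE) - 1L)
  active <- day <= admin_days[chain_pid]
  rows <- vector("list", pr$max_refills)
  for (it in seq_len(pr$max_refills)) {
    if (!any(active)) break
    idx <- which(active)
    rows[[it]] <- data.table::data.table(pid = chain_pid[idx], day = day[idx],
                                         cls = chain_cls[idx])
    gap <- pr$refill_gap[1L] +
      sample.int(pr$refill_gap[2L] - pr$refill_gap[1L] + 1L, length(idx),
                 replace = TRUE) - 1L
    u <- stats::runif(length(idx))
    stopping <- u < pr$stop_prob
    switching <- multi_class & !stopping & u < pr$stop_prob + pr$switch_prob
    resume <- stopping & stats::runif(length(idx)) < pr$resume_prob
    gap[resume] <- pr$resume_gap[1L] +
      sample.int(pr$resume_gap[2L] - pr$resume_gap[1L] + 1L, sum(resume),
                 replace = TRUE) - 1L
    if (any(switching)) {
      sw <- idx[switching]
      new_cls <- draw_class(length(sw))
      clash <- new_cls == chain_cls[sw]
      while (any(clash)) {
        new_cls[clash] <- draw_class(sum(clash))
        clash <- new_cls == chain_cls[sw]
      }
      chain_cls[sw] <- new_cls
    }
    day[idx] <- day[idx] + gap
    active[idx[stopping & !resume]] <- FALSE
    active[idx] <- active[idx] & day[idx] <= admin_days[chain_pid[idx]]
  }
  data.table::rbindlist(rows)
}

# Draw cancer event days from piecewise-constant hazards on the 120-day
# grid: within each interval the log hazard is the sex-specific baseline
# plus the true log rate ratios of the person's current cumulative-duration
# category for each insulin class (evaluated at the interval start, exactly
# as the analysis does).
simulate_cancer <- function(person_id, index_date, sex, horizon_days,
                            ep, scenario) {
  n <- length(person_id)
  scheme <- category_scheme("broad")
  n_int <- as.integer(ceiling(horizon_days / 120))
  pid <- rep(seq_len(n), n_int)
  k <- sequence(n_int) - 1L
  start <- k * 120L
  end <- pmin(start + 120L, horizon_days[pid])
  grid <- data.table::data.table(pid = pid, start = start,
                                 days = as.numeric(end - start))
  queries <- data.table::data.table(person_id = person_id[pid],
                                    t_query = start)
  mult <- numeric(nrow(grid))
  for (cl in c("human", "glargine", "detemir")) {
    g <- grid_cum_days(ep, queries, cl)
    idx <- categorize_index(g$cum, scheme, g$ever)
    eff_by_level <- c(0, unname(scenario$true_log_rr[[cl]][scheme$labels]))
    mult <- mult + eff_by_level[idx]
  }
  haz <- scenario$baseline_hazards
  total <- c(male = sum(haz$men), female = sum(haz$women))
  base_day <- total[ifelse(sex == "male", "male", "female")] / 1000 / DAYS_PER_YEAR
  grid[, lambda := base_day[pid] * exp(mult)]
  grid[, cumhaz := lambda * days]
  grid[, cum_after := cumsum(cumhaz), by = pid]
  draw <- stats::rexp(n)
  grid[, hit := cum_after >= draw[pid]]
  cancer_day <- rep(NA_integer_, n)
  rows <- grid[hit == TRUE, .SD[1L], by = pid]
  if (nrow(rows)) {
    resid <- draw[rows$pid] - (rows$cum_after - rows$cumhaz)
    day_in <- pmin(floor(resid / rows$lambda), rows$days - 1)
    cancer_day[rows$pid] <- as.integer(rows$start + day_in)
  }
  cancer_day
}

#' Generate a synthetic registry bundle with known rate ratios
#'
#' Simulates the three registry tables for the five country cohorts of a
#' scenario: persons with realistic age/sex mixtures and per-country study
#' windows, refill chains of insulin prescriptions in 90-DDD amounts with
#' gaps, stops, resumptions and class switches, baseline co-medication, and
#' cancer incidence under piecewise-constant hazards multiplied by
#' `exp(true_log_rr)` of the person's current cumulative-duration category
#' per insulin class (evaluated on the same 120-day grid as the analysis).
#' Death and emigration censor follow-up; configurable fractions of persons
#' violate the lead-in, age or cancer-history criteria so that cohort
#' exclusions are exercised. Output is a pure function of
#' `(scenario, seed)`.
#'
#' @param scenario An `rx_scenario` from [null_scenario()] or
#'   [effect_scenario()].
#' @param seed RNG seed (defaults to `scenario$seed`).
#' @return List with `bundle` (a validated `rx_bundle`) and `truth` (an
#'   `rx_truth`: the scenario, seed, true log rate ratios and the realized
#'   per-person index/censoring/cancer days).
#' @export
generate_bundle <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  n_total <- sum(scenario$n_per_country)
  if (n_total == 0) stop("scenario population is empty")
  set.seed(as.integer(seed))
  dict <- default_dictionary()

  country <- rep(names(scenario$n_per_country), scenario$n_per_country)
  n <- length(country)
  person_id <- sprintf("P%06d", seq_len(n))
  sp <- scenario$study_period
  study_start <- sp$study_start[match(country, sp$country)]
  study_end <- sp$study_end[match(country, sp$country)]

  grp_probs <- c(eligible = 1 - sum(scenario$ineligible), scenario$ineligible)
  group <- names(grp_probs)[sample.int(length(grp_probs), n, replace = TRUE,
                                       prob = grp_probs)]
  names(group) <- NULL

  window <- as.integer(study_end - 90L - (study_start + 365L))
  index_date <- study_start + 365L +
    floor(stats::runif(n) * (window + 1L))
  short <- group == "short_leadin"
  index_date[short] <- study_start[short] + floor(stats::runif(sum(short)) * 365)

  band <- sample.int(nrow(scenario$age_bands), n, replace = TRUE,
                     prob = scenario$age_bands$prob)
  age <- scenario$age_bands$lo[band] +
    stats::runif(n) * (scenario$age_bands$hi[band] - scenario$age_bands$lo[band])
  under <- group == "underage"
  age[under] <- 10 + stats::runif(sum(under)) * 7.9
  birth_date <- index_date - round(age * DAYS_PER_YEAR)
  sex <- ifelse(stats::runif(n) < scenario$sex_ratio_male, "male", "female")

  data_start <- pmax(study_start, birth_date + 365L)
  data_end <- study_end
  admin_days <- as.integer(data_end - index_date)

  # censoring draws
  h <- scenario$censoring_hazards / 1000 / DAYS_PER_YEAR
  death_day <- floor(stats::rexp(n, h[["death"]])) + 1L
  emig_day <- if (h[["emigration"]] > 0) {
    floor(stats::rexp(n, h[["emigration"]])) + 1L
  } else rep(.Machine$integer.max, n)
  pre_censor <- pmin(admin_days, death_day, emig_day)

  # prescriptions: insulin refill chains + baseline co-medication
  chains <- simulate_prescribing(n, admin_days, scenario$prescribing)
  rx <- chains[, .(person_id = person_id[pid],
                   dispense_date = index_date[pid] + day,
                   atc_code = c(human = "A10AB01", glargine = "A10AE04",
                                detemir = "A10AE05",
                                other_insulin = "A10AD02")[cls],
                   ddd_amount = scenario$prescribing$ddd_per_refill)]
  comed_codes <- c(niad = "A10BA02", statin = "C10AA01", nsaid = "M01AE01",
                   hrt = "G03CA03")
  comed_rows <- lapply(names(scenario$comed_probs), function(dr) {
    p <- scenario$comed_probs[[dr]]
    who <- which(stats::runif(n) < p)
    if (dr == "hrt") who <- who[sex[who] == "female"]
    if (!length(who)) return(NULL)
    d <- index_date[who] - sample.int(365L, length(who), replace = TRUE)
    data.table::data.table(person_id = person_id[who],
                           dispense_date = pmax(d, data_start[who]),
                           atc_code = comed_codes[[dr]], ddd_amount = 30)
  })
  old_statin <- which(stats::runif(n) < 0.10)
  if (length(old_statin)) {
    d <- index_date[old_statin] - 365L -
      sample.int(335L, length(old_statin), replace = TRUE)
    comed_rows <- c(comed_rows, list(data.table::data.table(
      person_id = person_id[old_statin],
      dispense_date = pmax(d, data_start[old_statin]),
      atc_code = comed_codes[["statin"]], ddd_amount = 30)))
  }
  rx <- data.table::rbindlist(c(list(rx), comed_rows))
  data.table::setorder(rx, person_id, dispense_date, atc_code)

  # cancer under the scenario's exposure-category hazards
  ep <- insulin_episode_table(rx, data.table::data.table(
    person_id = person_id, index_date = index_date), dict)
  cancer_day <- simulate_cancer(person_id, index_date, sex, pre_censor,
                                ep, scenario)
  haz <- scenario$baseline_hazards
  draw_site <- function(sx, m) {
    p <- if (sx == "male") haz$men else haz$women
    haz$site[sample.int(nrow(haz), m, replace = TRUE, prob = p)]
  }
  site <- rep(NA_character_, n)
  for (sx in c("male", "female")) {
    who <- which(!is.na(cancer_day) & sex == sx)
    if (length(who)) site[who] <- draw_site(sx, length(who))
  }

  ev_rows <- list()
  has_ca <- which(!is.na(cancer_day))
  if (length(has_ca)) {
    ev_rows$cancer <- data.table::data.table(
      person_id = person_id[has_ca],
      event_date = index_date[has_ca] + cancer_day[has_ca],
      event_type = "cancer", diagnosis_code = site_icd10(site[has_ca]))
  }
  died <- which(death_day <= admin_days & death_day <= emig_day)
  if (length(died)) {
    ev_rows$death <- data.table::data.table(
      person_id = person_id[died], event_date = index_date[died] + death_day[died],
      event_type = "death", diagnosis_code = "")
  }
  left <- which(emig_day <= admin_days & emig_day < death_day)
  if (length(left)) {
    ev_rows$emigration <- data.table::data.table(
      person_id = person_id[left], event_date = index_date[left] + emig_day[left],
      event_type = "emigration", diagnosis_code = "")
  }
  prior <- which(group == "prior_cancer")
  if (length(prior)) {
    d <- index_date[prior] - 100L - sample.int(900L, length(prior), replace = TRUE)
    d <- pmax(d, data_start[prior] + 1L)
    psite <- character(length(prior))
    for (sx in c("male", "female")) {
      who <- which(sex[prior] == sx)
      if (length(who)) psite[who] <- draw_site(sx, length(who))
    }
    ev_rows$prior <- data.table::data.table(
      person_id = person_id[prior], event_date = d,
      event_type = "cancer", diagnosis_code = site_icd10(psite))
  }
  nmsc <- which(stats::runif(n) < scenario$nmsc_history_prob)
  if (length(nmsc)) {
    d <- pmax(index_date[nmsc] - sample.int(800L, length(nmsc), replace = TRUE),
              data_start[nmsc] + 1L)
    ev_rows$nmsc <- data.table::data.table(
      person_id = person_id[nmsc], event_date = d,
      event_type = "cancer", diagnosis_code = "C44")
  }
  ev <- data.table::rbindlist(ev_rows)
  data.table::setorder(ev, person_id, event_date, event_type)

  persons <- data.table::data.table(
    person_id = person_id, sex = sex, birth_date = birth_date,
    country = country, data_start = data_start, data_end = data_end)

  bundle <- structure(list(persons = persons, prescriptions = rx, events = ev,
                           dictionary = dict,
                           study_period = data.table::copy(sp)),
                      class = "rx_bundle")
  validate_bundle(bundle)
  truth <- structure(list(
    scenario = scenario, seed = as.integer(seed),
    true_log_rr = scenario$true_log_rr,
    persons = data.table::data.table(
      person_id = person_id, group = group, index_date = index_date,
      pre_censor_day = pre_censor, cancer_day = cancer_day, site = site),
    episodes = ep),
    class = "rx_truth")
  list(bundle = bundle, truth = truth)
}
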