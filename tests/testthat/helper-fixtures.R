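# Hand-built registry fixtures, constructed in code.

d_ <- function(x) as.Date(x)

make_bundle <- function(persons, prescriptions = NULL, events = NULL,
                        study_period = NULL) {
  per <- data.table::as.data.table(persons)
  rx <- if (is.null(prescriptions)) {
    data.table::data.table(person_id = character(), dispense_date = as.Date(character()),
                           atc_code = character(), ddd_amount = numeric())
  } else data.table::as.data.table(prescriptions)
  ev <- if (is.null(events)) {
    data.table::data.table(person_id = character(), event_date = as.Date(character()),
                           event_type = character(), diagnosis_code = character())
  } else data.table::as.data.table(events)
  sp <- if (is.null(study_period)) {
    per[, .(study_start = min(data_start), study_end = max(data_end)),
        by = country]
  } else data.table::as.data.table(study_period)
  validate_bundle(structure(list(persons = per, prescriptions = rx, events = ev,
                                 dictionary = default_dictionary(),
                                 study_period = sp),
                            class = "rx_bundle"))
}

person_row <- function(id, sex = "male", birth = "1950-01-01", country = "DK",
                       start = "1996-01-01", end = "2010-12-31") {
  data.table::data.table(person_id = id, sex = sex, birth_date = d_(birth),
                         country = country, data_start = d_(start),
                         data_end = d_(end))
}

rx_row <- function(id, date, atc = "A10AB01", ddd = 90) {
  data.table::data.table(person_id = id, dispense_date = d_(date),
                         atc_code = atc, ddd_amount = ddd)
}

ev_row <- function(id, date, type = "cancer", code = "C18") {
  data.table::data.table(person_id = id, event_date = d_(date),
                         event_type = type,
                         diagnosis_code = if (type == "cancer") code else "")
}

# A 12-person bundle covering the cohort inclusion/censoring corner cases.
cohort_fixture <- function() {
  persons <- data.table::rbindlist(list(
    person_row("A", birth = "1950-01-01"),                      # included, cancer censor
    person_row("B", birth = "1950-01-01"),                      # short lead-in
    person_row("C", birth = "1990-01-01"),                      # aged 17.5 at index
    person_row("D", sex = "female", birth = "1948-01-01"),      # prior breast cancer
    person_row("E", birth = "1945-01-01"),                      # cancer on death date
    person_row("F", birth = "1940-01-01"),                      # type 2, comed flags
    person_row("G", birth = "1980-06-01"),                      # type 1 (young, no NIAD)
    person_row("H", birth = "1969-01-01"),                      # unspecified type
    person_row("I", birth = "1955-01-01"),                      # emigration censor
    person_row("J", sex = "female", birth = "1952-01-01"),      # same-day double cancer
    person_row("K", birth = "1960-01-01"),                      # man with HRT script
    person_row("L", birth = "1958-01-01")                       # cancer on index day
  ))
  prescriptions <- data.table::rbindlist(list(
    rx_row("A", "2000-01-01"),
    rx_row("B", "1996-06-06"),
    rx_row("C", "2007-07-02"),
    rx_row("D", "2005-01-01"),
    rx_row("E", "2001-01-01"),
    rx_row("F", "2003-01-01"), rx_row("F", "2002-09-01", atc = "A10BA02", ddd = 30),
    rx_row("F", "2002-06-15", atc = "C10AA01", ddd = 30),
    rx_row("F", "2001-01-05", atc = "M01AE01", ddd = 10),
    rx_row("G", "2004-01-01", atc = "A10AE04"),
    rx_row("H", "2004-01-01"),
    rx_row("I", "2005-01-01"),
    rx_row("J", "2002-01-01"),
    rx_row("K", "2004-01-01"), rx_row("K", "2003-11-01", atc = "G03CA03", ddd = 28),
    rx_row("L", "2005-06-01")
  ))
  events <- data.table::rbindlist(list(
    ev_row("A", "1999-06-01", code = "C44"),     # NMSC history: allowed
    ev_row("A", "2002-01-01", code = "C18"),
    ev_row("D", "1998-01-01", code = "C50"),
    ev_row("E", "2003-05-10", code = "C25"),
    ev_row("E", "2003-05-10", type = "death"),
    ev_row("I", "2006-01-01", type = "emigration"),
    ev_row("J", "2004-03-01", code = "C18"),
    ev_row("J", "2004-03-01", code = "C67"),
    ev_row("L", "2005-06-01", code = "C34")
  ))
  make_bundle(persons, prescriptions, events,
              study_period = data.table::data.table(
                country = "DK", study_start = d_("1996-01-01"),
                study_end = d_("2010-12-31")))
}

# Two identical men, one ending in colorectal cancer, one in death.
two_person_fixture <- function() {
  index <- d_("2001-01-01")
  persons <- data.table::rbindlist(list(
    person_row("P1", sex = "male", birth = "1940-01-01"),
    person_row("P2", sex = "male", birth = "1940-01-01")))
  rx <- data.table::rbindlist(list(
    rx_row("P1", "2001-01-01"), rx_row("P2", "2001-01-01")))
  ev <- data.table::rbindlist(list(
    ev_row("P1", as.character(index + 366), code = "C18"),
    ev_row("P2", as.character(index + 366), type = "death")))
  b <- make_bundle(persons, rx, ev,
                   study_period = data.table::data.table(
                     country = "DK", study_start = d_("1996-01-01"),
                     study_end = d_("2010-12-31")))
  asm <- assemble_cohort(b)
  list(bundle = b, cohort = asm$cohort)
}

# Random prescription histories for oracle-equivalence property tests.
random_exposure_person <- function(fu = 900L) {
  classes <- c("human", "glargine", "detemir")
  atc <- c(human = "A10AB01", glargine = "A10AE04", detemir = "A10AE05")
  rows <- lapply(classes, function(cl) {
    k <- sample(0:6, 1)
    if (k == 0) return(NULL)
    data.table::data.table(
      day = sort(sample(0:(fu - 1L), k)),
      class = cl, atc_code = atc[[cl]],
      ddd_amount = sample(c(14, 30, 60, 90, 100, 33.5), k, replace = TRUE))
  })
  data.table::rbindlist(rows)
}

# Minimal semi-aggregate table with declared keys, for direct model tests.
make_semiagg <- function(dt, keys, endpoint = "any_cancer", sex = "both") {
  dt <- data.table::as.data.table(dt)
  data.table::setattr(dt, "endpoint", endpoint)
  data.table::setattr(dt, "sex_stratum", sex)
  data.table::setattr(dt, "keys", keys)
  data.table::setattr(dt, "class", c("rx_semiagg", class(dt)))
  dt
}
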