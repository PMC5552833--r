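#' Default coding dictionary
#'
#' Returns the coding dictionary used throughout the package: ATC codes of
#' the insulin classes (human insulin, insulin glargine, insulin detemir,
#' other insulins), ICD-10 prefixes of the ten studied cancer sites plus
#' non-melanoma skin cancer, and ATC prefixes of the baseline co-medication
#' groups (non-insulin antidiabetic drugs, statins, NSAIDs, HRT).
#'
#' @return An object of class `rx_dictionary`: a list with elements
#'   `insulin_map` (named character vector, exact ATC code to insulin
#'   class), `site_map` (named character vector, ICD-10 prefix without dots
#'   to cancer site) and `comed_map` (named character vector, ATC prefix to
#'   co-medication group).
#' @export
#' @examples
#' d <- default_dictionary()
#' d$insulin_map[["A10AE04"]]
default_dictionary <- function() {
  insulin_map <- c(
    A10AC01 = "human", A10AB01 = "human", A10AD01 = "human",
    A10AE01 = "human", A10AF01 = "human",
    A10AE04 = "glargine",
    A10AE05 = "detemir"
  )
  site_map <- c(
    C33 = "lung", C34 = "lung",
    C43 = "melanoma",
    C67 = "bladder",
    C18 = "colorectal", C19 = "colorectal", C20 = "colorectal",
    C21 = "colorectal",
    C82 = "nhl", C83 = "nhl", C84 = "nhl", C85 = "nhl", C86 = "nhl",
    C884 = "nhl",
    C50 = "breast",
    C54 = "endometrial",
    C61 = "prostate",
    C22 = "liver",
    C25 = "pancreas",
    C44 = "nmsc"
  )
  comed_map <- c(A10B = "niad", C10A = "statin", M01A = "nsaid", G03 = "hrt")
  structure(list(insulin_map = insulin_map, site_map = site_map,
                 comed_map = comed_map),
            class = "rx_dictionary")
}

#' Insulin classes and cancer sites recognised by the package
#'
#' @return Character vectors of level names, in the order used for factors.
#' @export
insulin_classes <- function() c("human", "glargine", "detemir", "other_insulin")

#' @rdname insulin_classes
#' @export
cancer_sites <- function() {
  c("liver", "pancreas", "lung", "melanoma", "bladder", "colorectal",
    "nhl", "breast", "endometrial", "prostate", "nmsc", "other_cancer")
}

#' Classify an ATC code into an insulin class
#'
#' Exact codes from the dictionary map to their class; any other code under
#' the insulin group `A10A` is `other_insulin`; everything else is
#' `non_insulin`. Total function: never errors on a non-empty code.
#'
#' @param atc_code Character vector of ATC codes.
#' @param dictionary An `rx_dictionary` (default [default_dictionary()]).
#' @return Character vector with values in
#'   `c("human", "glargine", "detemir", "other_insulin", "non_insulin")`.
#' @export
#' @examples
#' classify_insulin(c("A10AE04", "A10AB01", "C10AA05"))
classify_insulin <- function(atc_code, dictionary = default_dictionary()) {
  stopifnot(is.character(atc_code), all(nzchar(atc_code)))
  out <- unname(dictionary$insulin_map[atc_code])
  a10a <- startsWith(atc_code, "A10A")
  out[is.na(out) & a10a] <- "other_insulin"
  out[is.na(out)] <- "non_insulin"
  out
}

#' Classify an ICD-10 code into a cancer site
#'
#' Dots are ignored (`"C88.4"` and `"C884"` are equivalent) and matching is
#' by longest dictionary prefix. `C44` maps to `nmsc`; valid codes with no
#' dictionary match map to `other_cancer`.
#'
#' @param icd10_code Character vector of ICD-10-style codes (letter followed
#'   by digits, optionally with one decimal point).
#' @inheritParams classify_insulin
#' @return Character vector of cancer sites (see [cancer_sites()]).
#' @export
#' @examples
#' classify_cancer_site(c("C61", "C88.4", "C44", "C19"))
classify_cancer_site <- function(icd10_code, dictionary = default_dictionary()) {
  stopifnot(is.character(icd10_code))
  code <- toupper(gsub(".", "", icd10_code, fixed = TRUE))
  ok <- grepl("^[A-Z][0-9]{2,}$", code)
  if (any(!ok)) {
    stop("not ICD-10-shaped code(s): ",
         paste(unique(icd10_code[!ok]), collapse = ", "))
  }
  site_map <- dictionary$site_map
  out <- rep("other_cancer", length(code))
  # longest-prefix match: try progressively shorter prefixes
  widths <- sort(unique(nchar(names(site_map))), decreasing = TRUE)
  unmatched <- rep(TRUE, length(code))
  for (w in widths) {
    pre <- substr(code, 1L, w)
    hit <- unmatched & pre %in% names(site_map)
    out[hit] <- unname(site_map[pre[hit]])
    unmatched[hit] <- FALSE
  }
  out
}

#' Map an ATC code to a baseline co-medication group
#'
#' @inheritParams classify_insulin
#' @return Character vector: `"niad"`, `"statin"`, `"nsaid"`, `"hrt"` or
#'   `NA` for codes outside the four groups.
#' @export
classify_comed <- function(atc_code, dictionary = default_dictionary()) {
  stopifnot(is.character(atc_code))
  out <- rep(NA_character_, length(atc_code))
  # order matters: A10B before G03 etc. is irrelevant here (disjoint prefixes)
  for (pre in names(dictionary$comed_map)) {
    hit <- is.na(out) & startsWith(atc_code, pre)
    out[hit] <- dictionary$comed_map[[pre]]
  }
  out
}

countries <- function() c("DK", "FI", "NO", "SE", "UK")

parse_iso_date <- function(x, what, file) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(sprintf("%s: unparsable %s date(s) at row(s) %s (e.g. '%s')",
                 file, what, paste(head(bad, 5L), collapse = ", "),
                 x[bad[1L]]), call. = FALSE)
  }
  if (anyNA(d)) {
    stop(sprintf("%s: missing %s date(s)", file, what), call. = FALSE)
  }
  d
}

check_columns <- function(dt, needed, file) {
  miss <- setdiff(needed, names(dt))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", file,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

#' Read a registry bundle from CSV files
#'
#' Reads and validates the three registry-style tables (persons,
#' prescriptions, clinical events) plus the coding dictionary, returning a
#' validated `rx_bundle`. Dates must be ISO-8601 (`YYYY-MM-DD`). Rows failing
#' type or referential checks abort the read with row-level diagnostics.
#'
#' The per-country study period (period of valid data collection) can be
#' supplied as a fourth CSV (`country,study_start,study_end`); when absent it
#' defaults to the observed range of `data_start`/`data_end` per country.
#'
#' @param persons,prescriptions,events Paths to the three CSV files.
#' @param dictionary Path to a dictionary JSON file, or an `rx_dictionary`
#'   object (default: the shipped dictionary).
#' @param study_period Optional path to a study-period CSV, or a data.frame
#'   with columns `country`, `study_start`, `study_end`.
#' @return An `rx_bundle`: list of data.tables `persons`, `prescriptions`,
#'   `events`, `study_period` plus the `dictionary`.
#' @seealso [write_bundle()], [validate_bundle()]
#' @export
read_bundle <- function(persons, prescriptions, events,
                        dictionary = default_dictionary(),
                        study_period = NULL) {
  per <- data.table::fread(persons, colClasses = list(character = "person_id"))
  rx <- data.table::fread(prescriptions,
                          colClasses = list(character = "person_id"))
  ev <- data.table::fread(events, colClasses = list(character = "person_id"))

  check_columns(per, c("person_id", "sex", "birth_date", "country",
                       "data_start", "data_end"), persons)
  check_columns(rx, c("person_id", "dispense_date", "atc_code",
                      "ddd_amount"), prescriptions)
  check_columns(ev, c("person_id", "event_date", "event_type",
                      "diagnosis_code"), events)

  per[, birth_date := parse_iso_date(as.character(birth_date), "birth", persons)]
  per[, data_start := parse_iso_date(as.character(data_start), "data_start", persons)]
  per[, data_end := parse_iso_date(as.character(data_end), "data_end", persons)]
  rx[, dispense_date := parse_iso_date(as.character(dispense_date),
                                       "dispense", prescriptions)]
  ev[, event_date := parse_iso_date(as.character(event_date), "event", events)]
  ev[, diagnosis_code := as.character(diagnosis_code)]
  ev[is.na(diagnosis_code), diagnosis_code := ""]

  if (is.character(dictionary)) dictionary <- read_dictionary(dictionary)

  if (is.character(study_period)) study_period <- data.table::fread(study_period)
  if (!is.null(study_period)) {
    study_period <- data.table::as.data.table(study_period)
    check_columns(study_period, c("country", "study_start", "study_end"),
                  "study_period")
    study_period[, study_start := as.Date(study_start)]
    study_period[, study_end := as.Date(study_end)]
  } else {
    study_period <- per[, .(study_start = min(data_start),
                            study_end = max(data_end)), by = country]
  }

  b <- structure(list(persons = per, prescriptions = rx, events = ev,
                      dictionary = dictionary,
                      study_period = study_period[order(country)]),
                 class = "rx_bundle")
  validate_bundle(b)
}

#' Validate a registry bundle
#'
#' Checks the bundle invariants: enum-valued sex/country, birth before
#' observation start, observation start not after end, positive DDD amounts,
#' prescriptions and events referring to known persons, dispense dates inside
#' the person's observation window, and non-empty diagnosis codes on cancer
#' events. Errors name the offending person ids or rows.
#'
#' @param bundle An `rx_bundle`.
#' @return The bundle, invisibly usable, after passing all checks.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "rx_bundle"))
  per <- bundle$persons; rx <- bundle$prescriptions; ev <- bundle$events

  if (anyDuplicated(per$person_id)) {
    stop("persons: duplicated person_id(s): ",
         paste(head(unique(per$person_id[duplicated(per$person_id)]), 5L),
               collapse = ", "))
  }
  bad <- per[!sex %in% c("male", "female"), person_id]
  if (length(bad)) stop("persons: invalid sex for: ",
                        paste(head(bad, 5L), collapse = ", "))
  bad <- per[!country %in% countries(), person_id]
  if (length(bad)) stop("persons: invalid country for: ",
                        paste(head(bad, 5L), collapse = ", "))
  bad <- per[!(birth_date < data_start & data_start <= data_end), person_id]
  if (length(bad)) stop("persons: need birth_date < data_start <= data_end for: ",
                        paste(head(bad, 5L), collapse = ", "))

  if (rx[, any(!is.finite(ddd_amount) | ddd_amount <= 0)]) {
    stop("prescriptions: ddd_amount must be positive; offending rows: ",
         paste(head(rx[, which(!is.finite(ddd_amount) | ddd_amount <= 0)], 5L),
               collapse = ", "))
  }
  unknown <- setdiff(rx$person_id, per$person_id)
  if (length(unknown)) {
    stop("prescriptions: unknown person_id(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  }
  unknown <- setdiff(ev$person_id, per$person_id)
  if (length(unknown)) {
    stop("events: unknown person_id(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  }
  win <- rx[per, on = "person_id",
            .(row = .I, ok = dispense_date >= data_start & dispense_date <= data_end)]
  if (win[, any(!ok)]) {
    stop("prescriptions: dispense_date outside observation window at row(s): ",
         paste(head(win[ok == FALSE, row], 5L), collapse = ", "))
  }
  if (ev[event_type == "cancer", any(!nzchar(diagnosis_code))]) {
    stop("events: cancer events must carry a diagnosis_code")
  }
  if (ev[, any(!event_type %in% c("cancer", "death", "emigration"))]) {
    stop("events: invalid event_type(s): ",
         paste(unique(setdiff(ev$event_type,
                              c("cancer", "death", "emigration"))), collapse = ", "))
  }
  bundle
}

#' Write a registry bundle to a directory of CSV files
#'
#' Writes `persons.csv`, `prescriptions.csv`, `events.csv`,
#' `study_period.csv` and `dictionary.json` with ISO-8601 dates and a
#' deterministic column order, such that [read_bundle()] reconstructs an
#' identical bundle.
#'
#' @param bundle An `rx_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "rx_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fwrite_iso <- function(dt, path) {
    out <- data.table::copy(dt)
    for (cl in names(out)) {
      if (inherits(out[[cl]], "Date")) out[, (cl) := format(get(cl), "%Y-%m-%d")]
    }
    data.table::fwrite(out, path)
  }
  fwrite_iso(bundle$persons[order(person_id)], file.path(dir, "persons.csv"))
  fwrite_iso(bundle$prescriptions[order(person_id, dispense_date, atc_code)],
             file.path(dir, "prescriptions.csv"))
  fwrite_iso(bundle$events[order(person_id, event_date, event_type)],
             file.path(dir, "events.csv"))
  fwrite_iso(bundle$study_period[order(country)],
             file.path(dir, "study_period.csv"))
  write_dictionary(bundle$dictionary, file.path(dir, "dictionary.json"))
  invisible(dir)
}

#' Read or write a coding dictionary as JSON
#'
#' @param path Path to a JSON file with elements `insulin_map`, `site_map`
#'   and `comed_map`, each an object of code-to-label pairs.
#' @return `read_dictionary()` returns an `rx_dictionary`;
#'   `write_dictionary()` returns `path` invisibly.
#' @export
read_dictionary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("insulin_map", "site_map", "comed_map") %in% names(x)))
  structure(list(insulin_map = unlist(x$insulin_map),
                 site_map = unlist(x$site_map),
                 comed_map = unlist(x$comed_map)),
            class = "rx_dictionary")
}

#' @rdname read_dictionary
#' @param dictionary An `rx_dictionary`.
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "rx_dictionary"))
  jsonlite::write_json(lapply(unclass(dictionary), as.list), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.rx_bundle <- function(x, ...) {
  cat("<rx_bundle>\n")
  cat(sprintf("  persons:       %d (%s)\n", nrow(x$persons),
              paste(x$persons[, .N, by = country][order(country),
                              sprintf("%s=%d", country, N)], collapse = ", ")))
  cat(sprintf("  prescriptions: %d\n", nrow(x$prescriptions)))
  cat(sprintf("  events:        %d\n", nrow(x$events)))
  invisible(x)
}
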