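test_that("ATC codes map onto insulin classes as a total partition", {
  expect_equal(classify_insulin("A10AE04"), "glargine")
  expect_equal(classify_insulin("A10AE05"), "detemir")
  expect_equal(classify_insulin(c("A10AC01", "A10AB01", "A10AD01", "A10AE01",
                                  "A10AF01")),
               rep("human", 5))
  expect_equal(classify_insulin(c("A10AD02", "A10AB04", "A10AE06")),
               rep("other_insulin", 3))
  expect_equal(classify_insulin(c("C10AA05", "A10BA02", "M01AE01")),
               rep("non_insulin", 3))
  # every A10A code lands in exactly one insulin class, never non_insulin
  some_a10a <- paste0("A10A", rep(LETTERS[1:6], each = 3), sprintf("%02d", 1:3))
  cls <- classify_insulin(some_a10a)
  expect_true(all(cls %in% c("human", "glargine", "detemir", "other_insulin")))
})

test_that("ICD-10 codes map onto cancer sites by dot-insensitive longest prefix", {
  expect_equal(classify_cancer_site("C61"), "prostate")
  expect_equal(classify_cancer_site("C88.4"), "nhl")
  expect_equal(classify_cancer_site("C884"), "nhl")
  expect_equal(classify_cancer_site("C44"), "nmsc")
  expect_equal(classify_cancer_site(c("C33", "C34", "C341")), rep("lung", 3))
  expect_equal(classify_cancer_site(c("C18", "C19", "C20", "C21")),
               rep("colorectal", 4))
  expect_equal(classify_cancer_site(c("C22", "C25", "C43", "C50", "C54", "C67")),
               c("liver", "pancreas", "melanoma", "breast", "endometrial",
                 "bladder"))
  expect_equal(classify_cancer_site(c("C71", "C97", "C880")),
               rep("other_cancer", 3))
  expect_error(classify_cancer_site("notacode"), "ICD-10")
})

test_that("the C00-C97 range is covered exhaustively and exclusively", {
  codes <- sprintf("C%02d", 0:97)
  sites <- classify_cancer_site(codes)
  expect_false(anyNA(sites))
  expect_true(all(sites %in% cancer_sites()))
  expect_equal(sum(sites == "nmsc"), 1L)  # C44 only
})

test_that("co-medication prefixes resolve and others return NA", {
  expect_equal(classify_comed(c("A10BA02", "C10AA01", "M01AE01", "G03CA03")),
               c("niad", "statin", "nsaid", "hrt"))
  expect_true(is.na(classify_comed("A10AB01")))
})

test_that("dictionary JSON round-trips", {
  p <- withr::local_tempfile(fileext = ".json")
  write_dictionary(default_dictionary(), p)
  expect_equal(read_dictionary(p), default_dictionary())
})

test_that("a bundle written to CSV re-reads as an equal bundle", {
  gen <- generate_bundle(null_scenario(n_total = 300), seed = 5)
  dir <- withr::local_tempdir()
  write_bundle(gen$bundle, dir)
  b2 <- read_bundle(file.path(dir, "persons.csv"),
                    file.path(dir, "prescriptions.csv"),
                    file.path(dir, "events.csv"),
                    dictionary = file.path(dir, "dictionary.json"),
                    study_period = file.path(dir, "study_period.csv"))
  for (tab in c("persons", "prescriptions", "events", "study_period")) {
    expect_equal(data.table::setorderv(data.table::copy(gen$bundle[[tab]]),
                                       names(gen$bundle[[tab]])),
                 data.table::setorderv(data.table::copy(b2[[tab]]),
                                       names(b2[[tab]])),
                 ignore_attr = TRUE)
  }
  expect_equal(b2$dictionary, gen$bundle$dictionary)
})

test_that("malformed input files fail with row-level diagnostics", {
  dir <- withr::local_tempdir()
  writeLines(c("person_id,sex,birth_date,country,data_start,data_end",
               "P1,male,1950-01-01,DK,1996-01-01,2010-12-31"),
             file.path(dir, "persons.csv"))
  writeLines(c("person_id,event_date,event_type,diagnosis_code"),
             file.path(dir, "events.csv"))

  # prescriptions referencing an unknown person
  writeLines(c("person_id,dispense_date,atc_code,ddd_amount",
               "GHOST,2000-01-01,A10AB01,90"),
             file.path(dir, "prescriptions.csv"))
  expect_error(read_bundle(file.path(dir, "persons.csv"),
                           file.path(dir, "prescriptions.csv"),
                           file.path(dir, "events.csv")),
               "GHOST")

  # unparsable date names the row
  writeLines(c("person_id,dispense_date,atc_code,ddd_amount",
               "P1,01/02/2000,A10AB01,90"),
             file.path(dir, "prescriptions.csv"))
  expect_error(read_bundle(file.path(dir, "persons.csv"),
                           file.path(dir, "prescriptions.csv"),
                           file.path(dir, "events.csv")),
               "unparsable")

  # missing column is a schema error
  writeLines(c("person_id,dispense_date,ddd_amount", "P1,2000-01-01,90"),
             file.path(dir, "prescriptions.csv"))
  expect_error(read_bundle(file.path(dir, "persons.csv"),
                           file.path(dir, "prescriptions.csv"),
                           file.path(dir, "events.csv")),
               "missing column")

  # non-positive DDD amounts are rejected
  writeLines(c("person_id,dispense_date,atc_code,ddd_amount",
               "P1,2000-01-01,A10AB01,0"),
             file.path(dir, "prescriptions.csv"))
  expect_error(read_bundle(file.path(dir, "persons.csv"),
                           file.path(dir, "prescriptions.csv"),
                           file.path(dir, "events.csv")),
               "positive")
})
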