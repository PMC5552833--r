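Package: rxcohort
Title: New-User Cohort and Cumulative-Exposure Rate-Ratio Analysis for
    Prescription Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-country pharmacoepidemiological cohort studies
    built from prescription and cancer-registry records. Implements a common
    data model for registry-style tables, a synthetic-registry generator with
    known exposure-outcome structure, new-user cohort assembly with a one-year
    lead-in, conversion of dispensed defined daily doses (DDDs) into
    time-varying cumulative-exposure categories on a 120-day grid,
    semi-aggregation of person-time into event/person-year tables, crude
    incidence rates with exact Poisson (Garwood) confidence intervals and
    small-cell suppression, and multivariable Poisson rate models with
    active-comparator rate-ratio contrasts and Wald confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
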