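#' Run the end-to-end pipeline from one configuration
#'
#' Orchestrates generate/read, cohort assembly, interval expansion,
#' aggregation, model fitting and reporting, writing deterministic CSV/JSON
#' outputs and a manifest to `out_dir`. Identical configuration and seed
#' give byte-identical outputs.
#'
#' Configuration fields (list or path to a JSON file):
#' * `mode`: `"synthetic"` (default) or `"bundle"`;
#' * `scenario`: for synthetic mode, optional path to a scenario JSON
#'   ([write_scenario()]); otherwise `n_total` and `rr` (optional)
#'   parameterise [null_scenario()]/[effect_scenario()];
#' * `paths`: for bundle mode, named list with `persons`, `prescriptions`,
#'   `events` and optionally `dictionary`, `study_period`;
#' * `scheme`: `"broad"` (default) or `"fine"`;
#' * `stockpile` (default TRUE) and `grace_days` (default 0): coverage
#'   options, see [coverage_episodes()];
#' * `endpoints`: endpoints to analyse (default any_cancer plus all sites);
#' * `sensitivity`: character vector of [run_sensitivity()] variants;
#' * `drop_country`: country for the `drop_cohort` variant;
#' * `seed`: RNG seed (synthetic mode).
#'
#' @param config List or path to a JSON configuration file.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  mode <- config$mode %||% "synthetic"
  seed <- as.integer(config$seed %||% 1L)
  scheme <- config$scheme %||% "broad"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (mode == "synthetic") {
    sc <- if (!is.null(config$scenario)) {
      read_scenario(config$scenario)
    } else if (!is.null(config$rr)) {
      effect_scenario(config$rr, n_total = as.integer(config$n_total %||% 20000L))
    } else {
      null_scenario(n_total = as.integer(config$n_total %||% 20000L))
    }
    gen <- generate_bundle(sc, seed = seed)
    bundle <- gen$bundle
  } else {
    p <- config$paths
    bundle <- read_bundle(p$persons, p$prescriptions, p$events,
                          dictionary = p$dictionary %||% default_dictionary(),
                          study_period = p$study_period)
  }

  asm <- assemble_cohort(bundle)
  cohort <- asm$cohort
  iv <- expand_cohort(cohort, bundle, scheme,
                      stockpile = config$stockpile %||% TRUE,
                      grace_days = config$grace_days %||% 0L)

  endpoints <- config$endpoints %||%
    c(setdiff(cancer_sites(), c("nmsc", "other_cancer")), "any_cancer")
  results <- run_main_analysis(cohort, bundle, scheme = scheme,
                               endpoints = endpoints, intervals = iv)
  rates <- data.table::rbindlist(lapply(endpoints, crude_rates, cohort = cohort))
  desc <- cohort_descriptives(cohort, bundle)

  write_out <- function(dt, name) {
    out <- data.table::copy(data.table::as.data.table(dt))
    for (cl in names(out)) {
      if (inherits(out[[cl]], "Date")) out[, (cl) := format(get(cl), "%Y-%m-%d")]
    }
    data.table::fwrite(out, file.path(out_dir, name))
  }
  write_out(cohort, "cohort.csv")
  write_out(asm$exclusions, "exclusions.csv")
  write_out(rates, "rates.csv")
  write_out(desc, "descriptives.csv")
  write_out(results, "results_rr.csv")
  agg_any <- aggregate_person_time(iv, cohort, "any_cancer")
  write_out(agg_any, "semi_aggregate.csv")

  sens <- config$sensitivity %||% character(0)
  for (v in sens) {
    sv <- run_sensitivity(cohort, bundle, variant = v,
                          country = config$drop_country, scheme = scheme)
    write_out(sv, paste0("results_rr_", v, ".csv"))
  }

  manifest <- list(
    mode = mode, seed = seed, scheme = scheme,
    stockpile = config$stockpile %||% TRUE,
    grace_days = config$grace_days %||% 0L,
    n_persons_bundle = nrow(bundle$persons),
    n_prescriptions = nrow(bundle$prescriptions),
    n_events = nrow(bundle$events),
    n_cohort = nrow(cohort),
    n_excluded = nrow(asm$exclusions),
    n_intervals = nrow(iv),
    n_aggregate_cells_any_cancer = nrow(agg_any),
    person_years = sum(cohort$follow_up_days) / DAYS_PER_YEAR,
    n_contrasts = nrow(results),
    endpoints = endpoints,
    sensitivity = sens)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
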