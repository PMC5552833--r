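#' One end-to-end synthetic replicate
#'
#' Generates a bundle from the scenario, assembles the cohort, expands it to
#' 120-day intervals, collapses to the semi-aggregate table for an endpoint
#' and fits the Poisson model. The unit of every simulation study in the
#' package.
#'
#' @param scenario An `rx_scenario`.
#' @param seed RNG seed for this replicate.
#' @param endpoint Endpoint to model (default `any_cancer`).
#' @param scheme Category scheme (default broad).
#' @return List with `fit` (`rx_fit`), `cohort`, `agg` and `truth`.
#' @export
run_replicate <- function(scenario, seed, endpoint = "any_cancer",
                          scheme = "broad") {
  gen <- generate_bundle(scenario, seed = seed)
  asm <- assemble_cohort(gen$bundle)
  iv <- expand_cohort(asm$cohort, gen$bundle, scheme,
                      episodes = gen$truth$episodes)
  agg <- aggregate_person_time(iv, asm$cohort, endpoint)
  fit <- suppressWarnings(fit_poisson_rates(agg))
  list(fit = fit, cohort = asm$cohort, agg = agg, truth = gen$truth)
}

#' Parameter-recovery simulation for a constant glargine effect
#'
#' Runs `n_reps` independent end-to-end replicates of an effect scenario and
#' records, per replicate, the inverse-variance pooled glargine-vs-human log
#' rate ratio across duration categories, its standard error, and whether
#' the pooled Wald 95% CI covers the true value.
#'
#' @param scenario An effect scenario (default [effect_scenario()] with
#'   RR 1.5 over 20,000 persons).
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @return data.table with one row per replicate: `rep`, `log_rr`, `se`,
#'   `covered`; `attr(,"true_log_rr")` records the simulated truth.
#' @export
mc_effect_recovery <- function(scenario = effect_scenario(1.5),
                               n_reps = 200L, seed = 1000L) {
  true_lrr <- unname(scenario$true_log_rr$glargine[1])
  rows <- lapply(seq_len(n_reps), function(i) {
    r <- run_replicate(scenario, seed = seed + i)
    pc <- pooled_contrast(r$fit, "glargine", "human")
    data.table::data.table(rep = i, log_rr = pc$log_rr, se = pc$se,
                           covered = log(pc$ci_lo) <= true_lrr &
                             true_lrr <= log(pc$ci_hi))
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "true_log_rr", true_lrr)
  out[]
}

#' Type-I error calibration under the null scenario
#'
#' Runs `n_reps` end-to-end replicates of a null scenario (all true rate
#' ratios 1) and records, per replicate, how many glargine-vs-human
#' duration-category Wald tests reject at the 5% level. Because category
#' contrasts within one fitted model are correlated, calibration should be
#' judged with replicate-level (cluster) Monte-Carlo standard errors; see
#' [mc_summary()].
#'
#' @param scenario A null scenario (default [null_scenario()]).
#' @inheritParams mc_effect_recovery
#' @return data.table with one row per replicate: `rep`, `n_contrasts`,
#'   `n_sig`, `frac_sig`.
#' @export
mc_null_calibration <- function(scenario = null_scenario(),
                                n_reps = 200L, seed = 2000L) {
  rows <- lapply(seq_len(n_reps), function(i) {
    r <- run_replicate(scenario, seed = seed + i)
    tab <- rr_table(r$fit, pairs = list(c("glargine", "human")))
    sig <- abs(tab$log_rr / tab$se) > stats::qnorm(0.975)
    data.table::data.table(rep = i, n_contrasts = nrow(tab),
                           n_sig = sum(sig), frac_sig = mean(sig))
  })
  data.table::rbindlist(rows)
}

#' Summarise a Monte-Carlo run
#'
#' For recovery output: mean and Monte-Carlo SE of the pooled log rate
#' ratio, and empirical CI coverage. For calibration output: overall
#' rejection fraction with its replicate-level (cluster) Monte-Carlo SE.
#'
#' @param x Output of [mc_effect_recovery()] or [mc_null_calibration()].
#' @return Named list of summary statistics.
#' @export
mc_summary <- function(x) {
  if ("covered" %in% names(x)) {
    list(mean_log_rr = mean(x$log_rr),
         mc_se = stats::sd(x$log_rr) / sqrt(nrow(x)),
         mean_rr = exp(mean(x$log_rr)),
         coverage = mean(x$covered),
         coverage_se = sqrt(mean(x$covered) * (1 - mean(x$covered)) / nrow(x)),
         n_reps = nrow(x),
         true_log_rr = attr(x, "true_log_rr"))
  } else {
    p <- sum(x$n_sig) / sum(x$n_contrasts)
    list(frac_sig = p,
         cluster_se = stats::sd(x$frac_sig) / sqrt(nrow(x)),
         n_reps = nrow(x),
         n_contrasts = sum(x$n_contrasts))
  }
}
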