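test_that("closed-form MLEs are reproduced exactly", {
  # single cell: intercept is the log crude rate
  one <- make_semiagg(
    data.table::data.table(events = 10L, person_years = 1000),
    keys = character(0))
  f1 <- fit_poisson_rates(one)
  expect_equal(unname(f1$coef[["(Intercept)"]]), log(10 / 1000),
               tolerance = 1e-10)

  # two cells differing in one binary term: coefficient is the crude log ratio
  two <- make_semiagg(
    data.table::data.table(niad = c(FALSE, TRUE), events = c(10L, 20L),
                           person_years = c(1000, 1000)),
    keys = "niad")
  f2 <- fit_poisson_rates(two)
  expect_equal(unname(f2$coef[["niadTRUE"]]), log(2), tolerance = 1e-10)
  expect_equal(unname(f2$coef[["(Intercept)"]]), log(0.01), tolerance = 1e-10)
})

test_that("the IRLS solver matches stats::glm at its fixed point", {
  # dense synthetic cell table: every factor level carries events, so the
  # MLE is finite and both solvers must agree tightly
  set.seed(77)
  lev <- category_scheme("broad")$levels
  n <- 2000
  cells <- data.table::data.table(
    exp_human = factor(sample(lev, n, TRUE), levels = lev),
    exp_glargine = factor(sample(lev, n, TRUE), levels = lev),
    exp_detemir = factor(sample(lev, n, TRUE), levels = lev),
    country = factor(sample(c("DK", "FI", "NO", "SE", "UK"), n, TRUE)),
    age_band = factor(sample(c("40-50", "50-60", "60-70"), n, TRUE)),
    niad = sample(c(TRUE, FALSE), n, TRUE),
    person_years = runif(n, 5, 50))
  eta <- log(0.02) + 0.3 * (cells$exp_glargine == "<=0.5") +
    0.2 * cells$niad - 0.1 * (cells$country == "UK")
  cells[, events := rpois(n, person_years * exp(eta))]
  tab <- make_semiagg(cells,
                      keys = c("exp_human", "exp_glargine", "exp_detemir",
                               "country", "age_band", "niad"))
  fit <- fit_poisson_rates(tab)
  g <- stats::glm(events ~ exp_human + exp_glargine + exp_detemir + country +
                    age_band + niad + offset(log(person_years)),
                  family = stats::poisson(), data = cells,
                  control = stats::glm.control(epsilon = 1e-13, maxit = 50))
  common <- intersect(names(stats::coef(g)), names(fit$coef))
  expect_equal(length(common), length(fit$coef))
  expect_lt(max(abs(stats::coef(g)[common] - fit$coef[common])), 1e-8)
  expect_lt(max(abs(stats::vcov(g)[common, common] -
                      fit$vcov[common, common])), 1e-8)
})

test_that("collapsed and uncollapsed data give identical coefficients", {
  g <- generate_bundle(null_scenario(n_total = 5000), seed = 23)
  asm <- assemble_cohort(g$bundle)
  iv <- expand_cohort(asm$cohort, g$bundle)
  agg <- aggregate_person_time(iv, asm$cohort, "any_cancer")
  fit_agg <- suppressWarnings(fit_poisson_rates(agg))

  # interval-level "table": one cell per interval row, nothing collapsed
  ev_ids <- asm$cohort$person_id[endpoint_for_site(asm$cohort, "any_cancer") == 1L]
  raw <- data.table::copy(iv)
  raw[, events := as.integer(last_interval & person_id %in% ev_ids)]
  raw[, person_years := person_days / 365.25]
  raw_tab <- make_semiagg(raw, keys = attr(agg, "keys"))
  fit_raw <- suppressWarnings(fit_poisson_rates(raw_tab))

  expect_equal(sort(names(fit_agg$coef)), sort(names(fit_raw$coef)))
  expect_lt(max(abs(fit_agg$coef - fit_raw$coef[names(fit_agg$coef)])), 1e-8)
})

test_that("rate-ratio contrasts are exp-differences with covariance-aware CIs", {
  fake <- structure(list(
    coef = c("exp_glargine<=0.5" = log(2), "exp_human<=0.5" = log(1.25)),
    vcov = diag(c(0.04, 0.01)) |>
      (\(m) { dimnames(m) <- list(c("exp_glargine<=0.5", "exp_human<=0.5"),
                                  c("exp_glargine<=0.5", "exp_human<=0.5")); m })(),
    exposure_levels = list(exp_glargine = c("non-exposed", "<=0.5"),
                           exp_human = c("non-exposed", "<=0.5")),
    endpoint = "any_cancer", sex_stratum = "both"), class = "rx_fit")
  rc <- rr_contrast(fake, "glargine", "human", "<=0.5")
  expect_equal(rc$rr, 1.6)
  expect_equal(rc$se, sqrt(0.05))
  # identity contrast degenerates at 1
  self <- rr_contrast(fake, "glargine", "glargine", "<=0.5")
  expect_equal(self$rr, 1)
  expect_equal(self$ci_lo, 1)
  expect_equal(self$ci_hi, 1)
  # contrasting at the reference level is exactly null
  ref <- rr_contrast(fake, "glargine", "human", "non-exposed")
  expect_equal(ref$rr, 1)
  expect_error(rr_contrast(fake, "glargine", "human", "5-6"), "not present")
})

test_that("contrast symmetry: RR(a,b) is the reciprocal of RR(b,a)", {
  r <- run_replicate(null_scenario(n_total = 2000), seed = 29)
  ab <- rr_table(r$fit, pairs = list(c("glargine", "human")))
  ba <- rr_table(r$fit, pairs = list(c("human", "glargine")))
  expect_equal(ab$rr, 1 / ba$rr)
  expect_equal(ab$ci_lo, 1 / ba$ci_hi)
  expect_equal(ab$ci_hi, 1 / ba$ci_lo)
})

test_that("main analysis respects sex restrictions and covariates", {
  g <- generate_bundle(null_scenario(n_total = 6000), seed = 31)
  asm <- assemble_cohort(g$bundle)
  iv <- expand_cohort(asm$cohort, g$bundle)
  res <- suppressMessages(run_main_analysis(
    asm$cohort, g$bundle, endpoints = c("prostate", "breast", "any_cancer"),
    intervals = iv))
  expect_true(all(res[endpoint == "prostate", sex] == "male"))
  expect_true(all(res[endpoint == "breast", sex] == "female"))
  expect_setequal(res[endpoint == "any_cancer", unique(sex)],
                  c("male", "female"))
  expect_true(all(res$rr > 0))
  expect_true(all(res$ci_lo < res$rr & res$rr < res$ci_hi))

  # secondary configuration: sexes combined
  res2 <- suppressMessages(run_main_analysis(
    asm$cohort, g$bundle, endpoints = "any_cancer", stratify_sex = FALSE,
    intervals = iv))
  expect_true(all(res2$sex == "both"))
})

test_that("sensitivity variants restrict or augment as specified", {
  g <- generate_bundle(null_scenario(n_total = 2500), seed = 37)
  asm <- assemble_cohort(g$bundle)
  co <- asm$cohort

  # dropping a country removes it from the analysis set
  res_dk <- suppressMessages(run_sensitivity(co, g$bundle, "drop_cohort",
                                             country = "UK",
                                             endpoints = "any_cancer"))
  direct <- suppressMessages(run_main_analysis(co[country != "UK"], g$bundle,
                                               endpoints = "any_cancer"))
  expect_equal(res_dk, direct, ignore_attr = TRUE)

  # restricting to post-2000 entry equals the main analysis when it is a no-op
  post <- co[index_date >= as.Date("2000-01-01")]
  res_idx <- suppressMessages(run_sensitivity(post, g$bundle, "index_ge_2000",
                                              endpoints = "any_cancer"))
  res_main <- suppressMessages(run_main_analysis(post, g$bundle,
                                                 endpoints = "any_cancer"))
  expect_equal(res_idx, res_main, ignore_attr = TRUE)

  # an empty restriction is handled, not crashed
  none <- co[diabetes_type == "type1"][0]
  expect_message(out <- run_sensitivity(none, g$bundle, "t2d_only"),
                 "empty cohort")
  expect_equal(nrow(out), 0L)

  # menopausal adjustment runs on the women-only endpoints (with the age-50
  # proxy it is collinear with the age bands and adds no information)
  res_men <- suppressWarnings(suppressMessages(
    run_sensitivity(co, g$bundle, "adjust_menopause", endpoints = "breast")))
  expect_true(nrow(res_men) >= 0)
})

test_that("the other-insulin timeline enters the model only on request", {
  g <- generate_bundle(null_scenario(n_total = 2000), seed = 41)
  asm <- assemble_cohort(g$bundle)
  iv <- expand_cohort(asm$cohort, g$bundle)
  agg0 <- aggregate_person_time(iv, asm$cohort, "any_cancer")
  fit0 <- suppressWarnings(fit_poisson_rates(agg0))
  expect_false("exp_other_insulin" %in% names(fit0$exposure_levels))
  agg1 <- aggregate_person_time(iv, asm$cohort, "any_cancer",
                                include_other = TRUE)
  fit1 <- suppressWarnings(fit_poisson_rates(agg1))
  expect_true("exp_other_insulin" %in% names(fit1$exposure_levels))
  expect_true(any(startsWith(names(fit1$coef), "exp_other_insulin")))
})

test_that("endpoints without events are skipped with a message", {
  x <- two_person_fixture()
  iv <- expand_cohort(x$cohort, x$bundle)
  expect_message(
    res <- run_main_analysis(x$cohort, x$bundle, endpoints = "melanoma",
                             intervals = iv),
    "no events")
  expect_equal(nrow(res), 0L)
})
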