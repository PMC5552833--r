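#' Fit a multivariable Poisson rate model on a semi-aggregate table
#'
#' Maximises the Poisson likelihood for the cell event counts with
#' `log(person_years)` as offset (log link), so coefficients are log rates.
#' Each insulin exposure enters as a categorical term whose reference level
#' is that insulin's own `non-exposed` category; the active-comparator
#' contrasts between insulins are formed afterwards from the coefficients
#' and their covariance ([rr_contrast()]). Remaining covariates are the
#' table's stratification keys. Unused factor levels are dropped (with a
#' warning when an exposure category disappears); covariates left with a
#' single level are removed. Convergence is declared at a relative deviance
#' change below 1e-12; non-convergence and aliased terms are errors.
#'
#' @param semiagg An `rx_semiagg` table from [aggregate_person_time()].
#' @return An `rx_fit`: list with `coef`, `vcov`, `deviance`, `iter`,
#'   `endpoint`, `sex_stratum`, `exposure_levels` (levels retained per
#'   insulin class), `dropped_terms` and the model `formula`.
#' @export
fit_poisson_rates <- function(semiagg) {
  if (!inherits(semiagg, "rx_semiagg")) stop("need an rx_semiagg table")
  if (sum(semiagg$events) == 0) stop("no events in table; cannot fit")
  dt <- data.table::as.data.table(semiagg)
  keys <- attr(semiagg, "keys")
  # every exposure factor present among the strata enters the model; the
  # other-insulin timeline participates only when the table was built with
  # include_other
  exp_terms <- grep("^exp_", keys, value = TRUE)
  covs <- setdiff(keys, exp_terms)

  dropped <- character(0)
  for (cl in c(exp_terms, covs)) {
    if (is.factor(dt[[cl]])) {
      before <- levels(dt[[cl]])
      dt[, (cl) := droplevels(get(cl))]
      gone <- setdiff(before, levels(dt[[cl]]))
      if (length(gone) && cl %in% exp_terms) {
        warning(sprintf("%s: empty exposure level(s) dropped: %s", cl,
                        paste(gone, collapse = ", ")), call. = FALSE)
      }
    }
  }
  keep_cov <- vapply(covs, function(cl) {
    v <- dt[[cl]]
    length(unique(v)) > 1L
  }, logical(1))
  dropped <- covs[!keep_cov]
  covs <- covs[keep_cov]
  keep_exp <- vapply(exp_terms, function(cl) nlevels(dt[[cl]]) > 1L, logical(1))
  exp_terms <- exp_terms[keep_exp]

  rhs <- paste(c(exp_terms, covs), collapse = " + ")
  fml <- stats::as.formula(paste("~", if (nzchar(rhs)) rhs else "1"))
  X <- stats::model.matrix(fml, data = dt)
  # aliased covariate columns (e.g. a menopause indicator that coincides
  # exactly with the age bands) are dropped with a warning; an aliased
  # exposure term is an error, since the contrasts would be meaningless
  for (attempt in 1:3) {
    fit <- tryCatch(irls_poisson(X, dt$events, log(dt$person_years)),
                    rx_alias_error = function(e) e)
    if (!inherits(fit, "rx_alias_error")) break
    bad <- fit$aliased
    if (any(startsWith(bad, "exp_"))) {
      stop("rank-deficient design; aliased exposure term(s): ",
           paste(bad[startsWith(bad, "exp_")], collapse = ", "))
    }
    warning("dropping aliased covariate column(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
    X <- X[, setdiff(colnames(X), bad), drop = FALSE]
  }
  if (inherits(fit, "rx_alias_error")) stop(fit)
  exposure_levels <- lapply(stats::setNames(exp_terms, exp_terms),
                            function(cl) levels(dt[[cl]]))
  structure(list(coef = fit$coef, vcov = fit$vcov, deviance = fit$deviance,
                 iter = fit$iter, converged = fit$converged,
                 endpoint = attr(semiagg, "endpoint"),
                 sex_stratum = attr(semiagg, "sex_stratum"),
                 exposure_levels = exposure_levels,
                 dropped_terms = dropped,
                 n_cells = nrow(dt), n_events = sum(dt$events),
                 formula = fml),
            class = "rx_fit")
}

#' @export
print.rx_fit <- function(x, ...) {
  cat(sprintf("<rx_fit> endpoint=%s sex=%s cells=%d events=%d coef=%d deviance=%.2f\n",
              x$endpoint, x$sex_stratum, x$n_cells, x$n_events,
              length(x$coef), x$deviance))
  invisible(x)
}

exposure_coef <- function(fit, class, category) {
  term <- paste0("exp_", class)
  lev <- fit$exposure_levels[[term]]
  if (is.null(lev) || !category %in% lev) {
    stop(sprintf("category '%s' not present for %s in this fit",
                 category, class))
  }
  name <- paste0(term, category)
  if (category == lev[1L]) {
    list(est = 0, name = NA_character_)   # reference level
  } else {
    if (!name %in% names(fit$coef)) {
      stop("coefficient not found: ", name)
    }
    list(est = unname(fit$coef[name]), name = name)
  }
}

#' Rate-ratio contrast between two insulin classes at one duration category
#'
#' The rate ratio is `exp(beta_a - beta_b)` where `beta_x` is the
#' coefficient of insulin `x` at the requested cumulative-duration category
#' (zero at the reference `non-exposed` level); the Wald 95% CI uses
#' `SE^2 = Var(beta_a) + Var(beta_b) - 2 Cov(beta_a, beta_b)`.
#'
#' @param fit An `rx_fit` from [fit_poisson_rates()].
#' @param insulin_a,insulin_b Insulin classes to contrast (`a` vs `b`).
#' @param category Duration category label (present for both insulins).
#' @param level Confidence level (default 0.95).
#' @return One-row data.table: `insulin_a`, `insulin_b`, `category`,
#'   `log_rr`, `se`, `rr`, `ci_lo`, `ci_hi`.
#' @export
rr_contrast <- function(fit, insulin_a, insulin_b, category, level = 0.95) {
  a <- exposure_coef(fit, insulin_a, category)
  b <- exposure_coef(fit, insulin_b, category)
  est <- a$est - b$est
  v <- 0
  if (!is.na(a$name)) v <- v + fit$vcov[a$name, a$name]
  if (!is.na(b$name)) v <- v + fit$vcov[b$name, b$name]
  if (!is.na(a$name) && !is.na(b$name)) {
    v <- v - 2 * fit$vcov[a$name, b$name]
  }
  if (insulin_a == insulin_b) { est <- 0; v <- 0 }
  se <- sqrt(pmax(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.table::data.table(
    insulin_a = insulin_a, insulin_b = insulin_b, category = category,
    log_rr = est, se = se, rr = exp(est),
    ci_lo = exp(est - z * se), ci_hi = exp(est + z * se))
}

#' All pairwise duration-specific rate-ratio contrasts of a fit
#'
#' Emits glargine-vs-human, detemir-vs-human and glargine-vs-detemir
#' contrasts at every exposed duration category present for both classes.
#'
#' @param fit An `rx_fit`.
#' @param pairs List of `c(a, b)` class pairs (default the three
#'   active-comparator pairs).
#' @return data.table of [rr_contrast()] rows with `endpoint` and `sex`.
#' @export
rr_table <- function(fit, pairs = list(c("glargine", "human"),
                                       c("detemir", "human"),
                                       c("glargine", "detemir"))) {
  out <- list()
  for (p in pairs) {
    la <- fit$exposure_levels[[paste0("exp_", p[1])]]
    lb <- fit$exposure_levels[[paste0("exp_", p[2])]]
    cats <- setdiff(intersect(la, lb), "non-exposed")
    for (ct in cats) {
      out[[length(out) + 1L]] <- rr_contrast(fit, p[1], p[2], ct)
    }
  }
  res <- data.table::rbindlist(out)
  if (nrow(res)) {
    res[, endpoint := fit$endpoint]
    res[, sex := fit$sex_stratum]
    data.table::setcolorder(res, c("endpoint", "sex"))
  }
  res
}

#' Inverse-variance pooled contrast across duration categories
#'
#' Pools the per-category log rate ratios of one class pair into a single
#' estimate with weights `1/SE^2`, propagating the full covariance of the
#' category contrasts (they share reference coefficients and are
#' correlated).
#'
#' @inheritParams rr_contrast
#' @return One-row data.table: `log_rr`, `se`, `rr`, `ci_lo`, `ci_hi`,
#'   `n_categories`.
#' @export
pooled_contrast <- function(fit, insulin_a = "glargine", insulin_b = "human",
                            level = 0.95) {
  la <- fit$exposure_levels[[paste0("exp_", insulin_a)]]
  lb <- fit$exposure_levels[[paste0("exp_", insulin_b)]]
  cats <- setdiff(intersect(la, lb), "non-exposed")
  if (!length(cats)) stop("no common exposed categories to pool")
  p <- length(fit$coef)
  C <- matrix(0, nrow = length(cats), ncol = p,
              dimnames = list(cats, names(fit$coef)))
  d <- numeric(length(cats))
  for (i in seq_along(cats)) {
    a <- exposure_coef(fit, insulin_a, cats[i])
    b <- exposure_coef(fit, insulin_b, cats[i])
    if (!is.na(a$name)) C[i, a$name] <- 1
    if (!is.na(b$name)) C[i, b$name] <- C[i, b$name] - 1
    d[i] <- a$est - b$est
  }
  S <- C %*% fit$vcov %*% t(C)
  w <- 1 / diag(S)
  est <- sum(w * d) / sum(w)
  v <- as.numeric(t(w) %*% S %*% w) / sum(w)^2
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.table::data.table(insulin_a = insulin_a, insulin_b = insulin_b,
                         log_rr = est, se = se, rr = exp(est),
                         ci_lo = exp(est - z * se), ci_hi = exp(est + z * se),
                         n_categories = length(cats))
}

#' Run the main duration-specific rate-ratio analysis
#'
#' For every requested endpoint and applicable sex stratum: collapse the
#' interval rows to a semi-aggregate table, fit the Poisson model and emit
#' all pairwise insulin contrasts at every duration category. The primary
#' configuration stratifies by sex and uses the broad category scheme; the
#' secondary configuration (`stratify_sex = FALSE`, `scheme = "fine"`)
#' combines the sexes (sex-specific endpoints keep their single sex) with
#' finer duration categories. Endpoints or strata without events are
#' skipped with a message.
#'
#' @param cohort,bundle Cohort and its source bundle.
#' @param scheme Category scheme (default `"broad"`).
#' @param endpoints Endpoints to analyse (default the ten sites plus
#'   `any_cancer`).
#' @param stratify_sex Fit separate models for men and women (default TRUE).
#' @param menopause Add menopausal status to breast/endometrial models.
#' @param intervals Optional precomputed [expand_cohort()] table.
#' @return data.table of contrast rows (see [rr_table()]) for all
#'   endpoint x stratum models, with a `comparisons` attribute counting the
#'   emitted contrasts (no multiplicity correction is applied).
#' @export
run_main_analysis <- function(cohort, bundle, scheme = "broad",
                              endpoints = c(setdiff(cancer_sites(), c("nmsc", "other_cancer")),
                                            "any_cancer"),
                              stratify_sex = TRUE, menopause = FALSE,
                              intervals = NULL) {
  if (is.null(intervals)) intervals <- expand_cohort(cohort, bundle, scheme)
  out <- list()
  for (ep in endpoints) {
    strata <- if (endpoint_sex(ep) != "both") endpoint_sex(ep)
              else if (stratify_sex) c("male", "female") else "both"
    for (sx in strata) {
      agg <- aggregate_person_time(intervals, cohort, ep, sex_stratum = sx,
                                   menopause = menopause &&
                                     ep %in% c("breast", "endometrial"))
      if (sum(agg$events) == 0) {
        message("skipping ", ep, " (", sx, "): no events")
        next
      }
      # sparse endpoints can lack a finite MLE (all events outside some
      # exposure level); such strata are skipped, not fabricated
      fit <- tryCatch(suppressWarnings(fit_poisson_rates(agg)),
                      error = function(e) {
                        message("skipping ", ep, " (", sx, "): ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(fit)) next
      out[[paste(ep, sx)]] <- rr_table(fit)
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "comparisons", nrow(res))
  res[]
}

#' Sensitivity-analysis variants of the main analysis
#'
#' * `t2d_only`: restrict to persons meeting the type 2 diabetes criteria;
#' * `index_ge_2000`: drop persons with an index date before 2000-01-01;
#' * `drop_cohort`: remove one country (give `country`);
#' * `adjust_menopause`: add menopausal status to the breast and
#'   endometrial models.
#'
#' @param cohort,bundle Cohort and source bundle.
#' @param variant One of the four variant names.
#' @param country Country to drop for `drop_cohort`.
#' @param ... Passed to [run_main_analysis()].
#' @return As [run_main_analysis()]; empty table (with a message) when the
#'   restriction leaves nothing to analyse.
#' @export
run_sensitivity <- function(cohort, bundle,
                            variant = c("t2d_only", "index_ge_2000",
                                        "drop_cohort", "adjust_menopause"),
                            country = NULL, ...) {
  variant <- match.arg(variant)
  cohort <- data.table::as.data.table(cohort)
  menop <- FALSE
  if (variant == "t2d_only") {
    cohort <- cohort[diabetes_type == "type2"]
  } else if (variant == "index_ge_2000") {
    cohort <- cohort[index_date >= as.Date("2000-01-01")]
  } else if (variant == "drop_cohort") {
    if (is.null(country)) stop("drop_cohort needs a country")
    keep <- setdiff(unique(cohort$country), country)
    cohort <- cohort[country %in% keep]
  } else {
    menop <- TRUE
  }
  if (!nrow(cohort)) {
    message("sensitivity ", variant, ": empty cohort, nothing to analyse")
    return(data.table::data.table())
  }
  run_main_analysis(cohort, bundle, menopause = menop, ...)
}
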