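#' Cumulative-exposure category schemes
#'
#' Two schemes partition cumulative treatment time (in years, 365.25 days per
#' year) into ordered categories on top of a `non-exposed` level for persons
#' who never used the drug:
#'
#' * `broad`: half-year bins to 1 year, then 1-year bins, terminal open bin
#'   `>6` — `non-exposed, <=0.5, 0.5-1, 1-2, 2-3, 3-4, 4-5, 5-6, >6`.
#' * `fine`: half-year bins to 1 year, then 1-year bins with terminal open
#'   bin `9-10`.
#'
#' Bins are half-open on the left, `(lo, hi]`, with 0 days falling in the
#' first exposed bin (a person is exposed from the day of the first
#' dispensing onwards).
#'
#' @param name `"broad"` or `"fine"`.
#' @return An `rx_scheme`: list with `name`, `breaks` (year cut-points,
#'   ending in `Inf`), `labels` (exposed-category labels) and `levels`
#'   (factor levels: `non-exposed` followed by `labels`).
#' @export
#' @examples
#' category_scheme("broad")$levels
category_scheme <- function(name = c("broad", "fine")) {
  name <- match.arg(name)
  if (name == "broad") {
    breaks <- c(0, 0.5, 1, 2, 3, 4, 5, 6, Inf)
    labels <- c("<=0.5", "0.5-1", "1-2", "2-3", "3-4", "4-5", "5-6", ">6")
  } else {
    breaks <- c(0, 0.5, 1:9, Inf)
    labels <- c("<=0.5", "0.5-1", "1-2", "2-3", "3-4", "4-5", "5-6", "6-7",
                "7-8", "8-9", "9-10")
  }
  structure(list(name = name, breaks = breaks, labels = labels,
                 levels = c("non-exposed", labels)),
            class = "rx_scheme")
}

DAYS_PER_YEAR <- 365.25

#' Categorise cumulative exposed days
#'
#' Maps cumulative exposed days to the scheme's duration category;
#' never-exposed persons map to `non-exposed` regardless of `cum_days`.
#'
#' @param cum_days Non-negative numeric vector of cumulative exposed days.
#' @param scheme An `rx_scheme` from [category_scheme()], or a scheme name.
#' @param ever_exposed Logical vector (recycled): has the person had any
#'   dispensing of this drug on or before the evaluation time?
#' @return Factor with levels `scheme$levels`.
#' @export
#' @examples
#' categorize_exposure(c(100, 2300), "broad", TRUE)
categorize_exposure <- function(cum_days, scheme = "broad", ever_exposed = TRUE) {
  if (is.character(scheme)) scheme <- category_scheme(scheme)
  if (any(cum_days < 0, na.rm = TRUE)) stop("cum_days must be non-negative")
  n <- max(length(cum_days), length(ever_exposed))
  cum_days <- rep_len(cum_days, n)
  ever_exposed <- rep_len(ever_exposed, n)
  idx <- categorize_index(cum_days, scheme, ever_exposed)
  structure(idx, levels = scheme$levels, class = "factor")
}

# integer level index into scheme$levels; 1 = non-exposed
categorize_index <- function(cum_days, scheme, ever_exposed) {
  # bins are (lo, hi] with 0 in the first exposed bin (include.lowest)
  idx <- pmax(findInterval(cum_days / DAYS_PER_YEAR, scheme$breaks,
                           left.open = TRUE), 1L) + 1L
  idx[!ever_exposed] <- 1L
  idx
}

# Decade age bands as used in the baseline tables; left-closed [lo, hi).
age_band_levels <- function() {
  c("18-30", "30-40", "40-50", "50-60", "60-70", "70-80", "80+")
}

age_band <- function(age_years) {
  cut(pmax(age_years, 18), breaks = c(18, 30, 40, 50, 60, 70, 80, Inf),
      labels = age_band_levels(), right = FALSE, include.lowest = TRUE)
}

# Duration of insulin-treated diabetes: whole years since index, capped at
# the scheme's terminal year so sparse synthetic cohorts keep full rank.
duration_band <- function(days_since_index, scheme) {
  cap <- max(scheme$breaks[is.finite(scheme$breaks)])
  yr <- pmin(as.integer(days_since_index / DAYS_PER_YEAR), cap)
  structure(yr + 1L, levels = as.character(0:cap), class = "factor")
}

# Baseline calendar time: 3-year bins of the index year, anchored at 1987
# (the earliest study window).
calendar_band <- function(index_date, width = 3L, anchor = 1987L) {
  y <- as.integer(format(index_date, "%Y"))
  lo <- anchor + width * ((y - anchor) %/% width)
  factor(sprintf("%d-%d", lo, lo + width - 1L),
         levels = sprintf("%d-%d", seq(anchor, 2030L, by = width),
                          seq(anchor, 2030L, by = width) + width - 1L))
}
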