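test_that("coverage episodes follow the 1-DDD/day rule with stockpiling", {
  expect_equal(coverage_episodes(0, 100),
               data.table::data.table(start = 0L, end = 100L))
  # purchase while covered extends from the coverage end
  expect_equal(coverage_episodes(c(0, 30), c(50, 50)),
               data.table::data.table(start = 0L, end = 100L))
  # purchase after a gap opens a new episode
  expect_equal(coverage_episodes(c(0, 60), c(30, 30)),
               data.table::data.table(start = c(0L, 60L), end = c(30L, 90L)))
  # abutting purchases merge into one episode
  expect_equal(coverage_episodes(c(0, 30), c(30, 30)),
               data.table::data.table(start = 0L, end = 60L))
  # fractional DDD amounts cover whole days (ceiling)
  expect_equal(coverage_episodes(0, 33.5),
               data.table::data.table(start = 0L, end = 34L))
  # truncation at follow-up end
  expect_equal(coverage_episodes(c(0, 200), c(50, 50), follow_up_end = 90),
               data.table::data.table(start = 0L, end = 50L))
  expect_error(coverage_episodes(c(30, 0), c(10, 10)), "sorted")
  expect_error(coverage_episodes(0, 0), "ddd_amount > 0")
})

test_that("no-stockpile and grace-period variants change coverage as documented", {
  # without stockpiling, leftover supply is discarded at the refill
  expect_equal(coverage_episodes(c(0, 30), c(50, 50), stockpile = FALSE),
               data.table::data.table(start = 0L, end = 80L))
  # a refill of less supply than remains never shortens coverage
  expect_equal(coverage_episodes(c(0, 10), c(100, 20), stockpile = FALSE),
               data.table::data.table(start = 0L, end = 100L))
  # a 10-day grace period bridges a 10-day gap (bridged days covered)
  expect_equal(coverage_episodes(c(0, 40), c(30, 30), grace_days = 10),
               data.table::data.table(start = 0L, end = 70L))
  expect_equal(coverage_episodes(c(0, 40), c(30, 30), grace_days = 9),
               data.table::data.table(start = c(0L, 40L), end = c(30L, 70L)))
})

test_that("cumulative exposed days freeze in gaps and resume on re-exposure", {
  ep <- coverage_episodes(c(0, 60), c(30, 30))
  expect_equal(cumulative_days_at(0, ep), 0)
  expect_equal(cumulative_days_at(15, ep), 15)
  expect_equal(cumulative_days_at(45, ep), 30)  # frozen in the gap
  expect_equal(cumulative_days_at(75, ep), 45)
  expect_equal(cumulative_days_at(1000, ep), 60)  # saturation
  expect_equal(cumulative_days_at(5, coverage_episodes(integer(), numeric())), 0)
})

test_that("duration categories partition cumulative time; never-users stay non-exposed", {
  expect_equal(as.character(categorize_exposure(100, "broad", TRUE)), "<=0.5")
  expect_equal(as.character(categorize_exposure(2300, "broad", TRUE)), ">6")
  expect_equal(as.character(categorize_exposure(2300, "fine", TRUE)), "6-7")
  expect_equal(as.character(categorize_exposure(0.5 * 365.25, "broad", TRUE)),
               "<=0.5")  # (lo, hi] bins: exactly half a year is still <=0.5
  expect_equal(as.character(categorize_exposure(0.5 * 365.25 + 1, "broad", TRUE)),
               "0.5-1")
  expect_equal(as.character(categorize_exposure(0, "broad", TRUE)), "<=0.5")
  expect_equal(as.character(categorize_exposure(0, "broad", FALSE)),
               "non-exposed")
  expect_equal(as.character(categorize_exposure(4000, "fine", TRUE)), "9-10")
  expect_error(categorize_exposure(-1, "broad", TRUE), "non-negative")
  # partition property: every (ever, cum_days) pair maps to exactly one level
  for (sch in c("broad", "fine")) {
    cats <- categorize_exposure(seq(0, 5000, by = 7), sch,
                                ever_exposed = TRUE)
    expect_false(anyNA(cats))
  }
})

make_one_person_bundle <- function(rx_days, rx_ddd, rx_atc, fu_days,
                                   sex = "female", birth = "1940-01-01") {
  index <- d_("2001-01-01")
  persons <- person_row("P1", sex = sex, birth = birth)
  rx <- data.table::data.table(person_id = "P1",
                               dispense_date = index + rx_days,
                               atc_code = rx_atc, ddd_amount = rx_ddd)
  ev <- ev_row("P1", as.character(index + fu_days), type = "death")
  b <- make_bundle(persons, rx, ev,
                   study_period = data.table::data.table(
                     country = "DK", study_start = d_("1996-01-01"),
                     study_end = d_("2010-12-31")))
  asm <- assemble_cohort(b)
  list(bundle = b, cohort = asm$cohort)
}

test_that("interval expansion partitions follow-up on the 120-day grid", {
  x <- make_one_person_bundle(0, 90, "A10AB01", 300)
  iv <- expand_cohort(x$cohort, x$bundle)
  expect_equal(iv$interval_start, c(0L, 120L, 240L))
  expect_equal(iv$person_days, c(120L, 120L, 60L))
  expect_equal(sum(iv$person_days), 300L)
  expect_equal(iv$last_interval, c(FALSE, FALSE, TRUE))
  # duration of insulin-treated diabetes advances in whole years
  expect_equal(as.character(iv$duration_band), c("0", "0", "0"))
})

test_that("a 400-DDD purchase at index crosses into 0.5-1 at the third interval", {
  x <- make_one_person_bundle(0, 400, "A10AE04", 360)
  iv <- expand_cohort(x$cohort, x$bundle)
  expect_equal(as.character(iv$exp_glargine), c("<=0.5", "<=0.5", "0.5-1"))
  expect_equal(iv$cum_glargine, c(0, 120, 240))
  expect_equal(as.character(iv$exp_human), rep("non-exposed", 3))
})

test_that("menopausal status flips at age 50 between interval starts", {
  index <- d_("2001-01-01")
  birth <- index - round(49.6 * 365.25)
  x <- make_one_person_bundle(0, 90, "A10AB01", 360, sex = "female",
                              birth = as.character(birth))
  iv <- expand_cohort(x$cohort, x$bundle)
  expect_equal(as.character(iv$menopausal_status), c("pre", "pre", "post"))
  y <- make_one_person_bundle(0, 90, "A10AB01", 360, sex = "male",
                              birth = as.character(birth))
  ivm <- expand_cohort(y$cohort, y$bundle)
  expect_equal(as.character(ivm$menopausal_status), rep("n/a", 3))
})

test_that("time before a class's first dispensing is non-exposed, never dropped", {
  # human insulin anchors the index at day 0; glargine starts at day 300
  x <- make_one_person_bundle(c(0, 300), c(90, 90), c("A10AB01", "A10AE04"),
                              500)
  iv <- expand_cohort(x$cohort, x$bundle)
  expect_equal(iv$interval_start, c(0L, 120L, 240L, 360L, 480L))
  expect_equal(sum(iv$person_days), 500L)
  # glargine person-time before day 300 sits in its non-exposed category
  expect_equal(as.character(iv$exp_glargine),
               c("non-exposed", "non-exposed", "non-exposed", "<=0.5", "<=0.5"))
  expect_equal(as.character(iv$exp_human)[1], "<=0.5")
})

test_that("the interval engine agrees with the day-level oracle on random persons", {
  set.seed(401)
  scheme <- category_scheme("broad")
  for (i in 1:60) {
    fu <- sample(200:900, 1)
    rx <- random_exposure_person(fu)
    if (is.null(rx) || nrow(rx) == 0) next
    grid <- seq(0L, fu - 1L, by = 120L)
    oracle <- day_level_oracle(rx, fu)
    for (cl in unique(rx$class)) {
      sub <- rx[class == cl][order(day)]
      ep <- coverage_episodes(sub$day, sub$ddd_amount, fu)
      eng_cum <- cumulative_days_at(grid, ep)
      orc <- oracle[class == cl][match(grid, day)]
      expect_equal(eng_cum, as.numeric(orc$cum_days_start))
      eng_cat <- categorize_exposure(eng_cum, scheme, grid >= min(sub$day))
      orc_cat <- categorize_exposure(orc$cum_days_start, scheme, orc$ever)
      expect_equal(eng_cat, orc_cat)
    }
  }
})

test_that("adding a prescription never decreases cumulative exposure", {
  set.seed(402)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    days <- sort(sample(0:600, k))
    ddd <- sample(c(30, 60, 90), k, replace = TRUE)
    drop <- sample(k, 1)
    ep_all <- coverage_episodes(days, ddd)
    ep_less <- coverage_episodes(days[-drop], ddd[-drop])
    t_grid <- seq(0, 800, by = 40)
    expect_true(all(cumulative_days_at(t_grid, ep_all) >=
                      cumulative_days_at(t_grid, ep_less)))
  }
})
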