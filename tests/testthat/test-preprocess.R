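test_that("noon-to-noon sleep attribution splits episodes at noon", {
  iv <- data.frame(start = as.POSIXct("2017-01-01 23:00", tz = "UTC"),
                   end = as.POSIXct("2017-01-02 07:00", tz = "UTC"))
  expect_equal(sleep_day_hours(iv, as.Date("2017-01-02")), 8)
  expect_equal(sleep_day_hours(iv[0, ], as.Date("2017-01-02")), 0)
  # nap across noon is split between adjacent days
  nap <- data.frame(start = as.POSIXct("2017-01-02 11:00", tz = "UTC"),
                    end = as.POSIXct("2017-01-02 13:00", tz = "UTC"))
  expect_equal(sleep_day_hours(nap, as.Date("2017-01-02")), 1)
  expect_equal(sleep_day_hours(nap, as.Date("2017-01-03")), 1)
  bad <- data.frame(
    start = as.POSIXct(c("2017-01-01 22:00", "2017-01-01 23:00"), tz = "UTC"),
    end = as.POSIXct(c("2017-01-02 01:00", "2017-01-02 07:00"), tz = "UTC"))
  expect_error(sleep_day_hours(bad, as.Date("2017-01-02")), "overlap")
})

test_that("long/short flags compare to the trailing 7-day window, sample SD", {
  # constant window: any exceedance is long, equality is not
  fl <- long_short_sleep_flags(c(rep(8, 7), 8.5))
  expect_identical(fl$long[8], 1L); expect_identical(fl$short[8], 0L)
  fl <- long_short_sleep_flags(c(rep(8, 7), 8.0))
  expect_identical(fl$long[8], 0L); expect_identical(fl$short[8], 0L)
  # alternating window, hand-computed mean 7.4286 / sd 0.5345
  win <- c(7, 8, 7, 8, 7, 8, 7)
  fl <- long_short_sleep_flags(c(win, 9))
  expect_identical(fl$long[8], 1L)
  fl <- long_short_sleep_flags(c(win, 7))
  expect_identical(fl$short[8], 0L)   # 7 > 6.894
  # fewer than 7 prior days: undefined, not zero
  fl <- long_short_sleep_flags(rep(8, 7))
  expect_true(all(is.na(fl$long)))
  # never both flags on one day
  set.seed(2)
  x <- rnorm(60, 8, 1.5)
  fl <- long_short_sleep_flags(x)
  both <- fl$long == 1L & fl$short == 1L
  expect_false(any(both, na.rm = TRUE))
})

test_that("weekly sleep dummy uses the any-day rule and ignores missing days", {
  expect_identical(weekly_sleep_dummy(rep(0L, 7)), 0L)
  expect_identical(weekly_sleep_dummy(c(0L, 1L, rep(0L, 5))), 1L)
  expect_identical(weekly_sleep_dummy(c(rep(NA_integer_, 6), 1L)), 1L)
  expect_identical(weekly_sleep_dummy(rep(NA_integer_, 7)), NA_integer_)
})

test_that("UV validity applies the 80% wear-time threshold (1152 min)", {
  expect_false(uv_daily_valid(1151L))
  expect_true(uv_daily_valid(1152L))
  expect_true(uv_daily_valid(1440L))
  expect_error(uv_daily_valid(1441L), "1440")
})

test_that("lunch-skip count ignores missing days and stays in 0..7", {
  expect_identical(lunch_skip_count(rep(1L, 7)), 0L)
  expect_identical(lunch_skip_count(rep(0L, 7)), 7L)
  expect_identical(lunch_skip_count(c(1L, 0L, 1L, 0L, 1L, 1L, 1L)), 2L)
  expect_identical(lunch_skip_count(c(0L, NA, 1L)), 1L)
})

test_that("per-patient standardisation gives mean 0, SD 1, zeros for constants", {
  expect_equal(standardise_series(c(0, 2, 4)), c(-1, 0, 1))
  set.seed(3)
  x <- rnorm(30, 5, 2); x[c(4, 9)] <- NA
  z <- standardise_series(x)
  expect_equal(mean(z, na.rm = TRUE), 0)
  expect_equal(sd(z, na.rm = TRUE), 1)
  expect_warning(z0 <- standardise_series(rep(3, 10)), "zero-variance")
  expect_equal(z0, rep(0, 10))
})

test_that("response transform is ln(K6+1)/sqrt(episodes) with monotonicity", {
  expect_equal(transform_response(0, 1), 0)
  expect_equal(transform_response(5, 4), log(6) / 2)
  expect_equal(transform_response(24, 1), log(25))
  expect_equal(round(transform_response(24, 1), 2), 3.22)
  expect_error(transform_response(5, 0), "episodes")
  # strictly increasing in K6, decreasing in episodes (K6 > 0)
  k6 <- 1:24
  expect_true(all(diff(transform_response(k6, 2)) > 0))
  expect_true(all(transform_response(6, 1:5) == sort(transform_response(6, 1:5),
                                                     decreasing = TRUE)))
})

test_that("seasonal and pseudo-positive dummies follow their definitions", {
  expect_identical(seasonal_dummy(as.Date(c("2016-12-15", "2017-01-03",
                                            "2017-06-10"))), c(1L, 1L, 0L))
  expect_identical(pseudo_positive_dummy(10L, 4L), 1L)
  expect_identical(pseudo_positive_dummy(9L, 4L), 0L)
  expect_identical(pseudo_positive_dummy(15L, 5L), 0L)
  expect_identical(pseudo_positive_dummy(10L, NA), NA_integer_)
})

test_that("build_panel assembles weeks from entry with carried PHQ-9 and weights", {
  ti <- tiny_inputs()
  # constant lunch/UV series trigger the documented zero-variance warnings
  p <- suppressWarnings(build_panel(ti$daily, ti$weekly, ti$profiles))
  expect_identical(nrow(p), 6L)
  expect_identical(p$weight, p$week)
  expect_equal(p$y, log(ti$weekly$k6_total + 1) / 2)
  # PHQ-9 observed at week 4 carries into weeks 5 and 6
  expect_true(all(is.na(p$phq9_carried[1:3])))
  expect_identical(p$phq9_carried[4:6], rep(4L, 3))
  # December/January entry: all six weeks are in season
  expect_identical(p$season, rep(1L, 6))
  # constant daily sleep: no flags after the lead-in window
  expect_identical(p$long_sleep, rep(0L, 6))
  # lunch always eaten
  expect_identical(p$lunch_skips, rep(0L, 6))
})

test_that("item-level questionnaire columns are validated against totals", {
  ti <- tiny_inputs(nw = 2L)
  wk <- ti$weekly
  items <- matrix(0L, 2, 6, dimnames = list(NULL, paste0("k6_item", 1:6)))
  items[1, 1:3] <- c(1L, 1L, 1L)
  wk <- cbind(wk, items)
  wk$k6_total <- c(3L, NA)                   # row 2 total comes from items
  p <- suppressWarnings(build_panel(ti$daily, wk, ti$profiles))
  expect_identical(p$k6_total, c(3L, 0L))
  wk$k6_total <- c(4L, 0L)                   # sum(items) = 3, not 4
  expect_error(suppressWarnings(build_panel(ti$daily, wk, ti$profiles)),
               "disagrees")
})

test_that("weekly aggregation conserves daily lunch-skip counts", {
  cfg <- cohort_config(n_patients = 8L, weeks = 10L, seed = 5L)
  co <- simulate_cohort(cfg)
  p <- build_panel(co$daily, co$weekly, co$profiles)
  study <- co$daily$date >= co$profiles$entry_date[match(co$daily$patient,
                                                         co$profiles$patient)]
  expect_identical(sum(p$lunch_skips), sum(co$daily$lunch_eaten[study] == 0L))
})
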