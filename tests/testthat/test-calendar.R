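test_that("occasions form a contiguous half-open 14-day grid", {
  cal <- build_occasion_calendar("2009-05-15", 2)
  expect_equal(cal$start_date, as.Date(c("2009-05-15", "2009-05-29")))
  expect_equal(cal$season, c("summer", "summer"))

  cal79 <- build_occasion_calendar("2009-05-15", 79)
  expect_equal(nrow(cal79), 79L)
  expect_true(all(diff(cal79$start_date) == 14))
  # start of the last occasion: origin + 78 * 14 days, well into May 2012
  expect_equal(cal79$start_date[79], as.Date("2012-05-11"))
  expect_equal(cal79$start_date,
               attr(cal79, "origin_date") + 14 * (cal79$occasion - 1))
})

test_that("season assignment follows the date windows with correct boundaries", {
  expect_equal(season_of_date(as.Date("2009-06-01")), "summer")
  expect_equal(season_of_date(as.Date("2009-10-24")), "winter")
  expect_equal(season_of_date(as.Date("2010-03-12")), "winter")
  expect_equal(season_of_date(as.Date("2010-03-13")), "spring")
  # the spring/summer overlap resolves by argument
  expect_equal(season_of_date(as.Date("2010-06-01"), overlap = "spring"),
               "spring")
})

test_that("season windows partition every day of a non-leap year", {
  days <- seq(as.Date("2010-01-01"), as.Date("2010-12-31"), by = "day")
  lab <- season_of_date(days)  # overlap resolved to summer
  expect_equal(length(lab), 365L)
  counts <- table(lab)
  # summer 15 May-1 Aug (79 d), autumn 2 Aug-23 Oct (83 d),
  # winter 24 Oct-12 Mar (140 d), spring 13 Mar-14 May only (63 d)
  expect_equal(as.integer(counts[c("summer", "autumn", "winter", "spring")]),
               c(79L, 83L, 140L, 63L))
})

test_that("season run lengths match the downstream seasonal period counts", {
  cal <- build_occasion_calendar("2009-05-15", 79,
                                 overlap_rule = "first_summer")
  runs <- season_run_lengths(cal)
  # after the first (extended) summer the annual cycle is 4/6/10/6
  expect_equal(runs$season[2:9],
               rep(c("autumn", "winter", "spring", "summer"), 2))
  expect_equal(runs$length[2:9], rep(c(6L, 10L, 6L, 4L), 2))
  expect_equal(sum(runs$length[5:8]), 26L)  # one full annual cycle
})

test_that("effort specification marks exactly the requested occasions", {
  cal <- study_calendar()
  expect_equal(sum(cal$effort == "none"), 4L)
  expect_equal(sum(cal$effort == "reduced"), 6L)
  expect_equal(sum(cal$effort == "full"), 69L)
  expect_true(all(cal$season[cal$effort != "full"] %in%
                    c("winter", "spring")))
})

test_that("calendar construction rejects invalid input", {
  expect_error(build_occasion_calendar("2009-05-15", 0), "positive integer")
  expect_error(build_occasion_calendar("2009-05-15", 10,
                                       effort_spec = list(none = 11)),
               "1..n_occasions")
  expect_error(build_occasion_calendar("2009-05-15", 10,
                                       effort_spec = list(none = 3,
                                                          reduced = 3)),
               "more than one regime")
})

test_that("release_occasion maps tagging dates with the half-open convention", {
  cal <- build_occasion_calendar("2009-05-15", 4)
  expect_equal(release_occasion("2009-05-20", cal), 1L)
  expect_equal(release_occasion("2009-05-29", cal), 2L)  # boundary start
  expect_equal(release_occasion("2009-06-05", cal), 2L)  # day 21 in [14, 28)
  expect_error(release_occasion("2009-05-14", cal), "outside")
  expect_error(release_occasion("2009-07-10", cal), "outside")
})

test_that("occasions tables and configs round-trip through files", {
  cal <- set_snow_days(study_calendar(), rep(0L, 79))
  path <- tempfile(fileext = ".csv")
  write_occasions(cal, path)
  cal2 <- read_occasions(path)
  expect_equal(cal2$season, cal$season)
  expect_equal(cal2$effort, cal$effort)
  expect_equal(cal2$start_date, cal$start_date)

  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("origin_date: 2009-05-15", "n_occasions: 79",
               "overlap_rule: summer", "effort_spec:",
               "  none: [18, 19, 20, 21]",
               "  reduced: [15, 16, 17, 46, 47, 48]"), cfg)
  cal3 <- calendar_from_config(cfg)
  expect_equal(cal3$effort, study_calendar()$effort)
  expect_equal(cal3$season, study_calendar()$season)
})
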