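write_generic_snow <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

write_dwd_snow <- function(dates, shk) {
  path <- tempfile(fileext = ".txt")
  lines <- c("STATIONS_ID;MESS_DATUM;QN_3;  FX;  FM;QN_4; RSK;RSKF; SDK;SHK_TAG;  NM; VPM;  PM; TMK; UPM; TXK; TNK; TGK;eor",
             sprintf("4349;%s;   10;   0;   0;   3; 0.0;   0; 0.0;%7d;   5; 5.0; 990; 1.0;  80; 3.0;-1.0;-2.0;eor",
                     format(dates, "%Y%m%d"), shk))
  writeLines(lines, path)
  path
}

test_that("generic snow CSVs parse and validate", {
  p <- write_generic_snow(data.frame(date = c("2009-12-01", "2009-12-02",
                                              "2009-12-03"),
                                     snow_cm = c(0, 2.5, NA)))
  s <- read_daily_snow(p, "generic_csv")
  expect_s3_class(s, "snow_series")
  expect_equal(nrow(s), 3L)
  expect_true(is.na(s$snow_cm[3]))

  p2 <- write_generic_snow(data.frame(date = c("2009-12-01", "2009-12-01"),
                                      snow_cm = c(0, 1)))
  expect_error(read_daily_snow(p2, "generic_csv"), "duplicated")
  p3 <- write_generic_snow(data.frame(date = "2009-12-01", snow_cm = -5))
  expect_error(read_daily_snow(p3, "generic_csv"), "negative")
})

test_that("DWD KL daily dialect maps the -999 sentinel to missing, not zero", {
  dates <- as.Date("2009-12-01") + 0:2
  p <- write_dwd_snow(dates, c(4L, -999L, 0L))
  s <- read_daily_snow(p, "dwd_kl_daily")
  expect_equal(s$snow_cm, c(4, NA, 0))
  expect_equal(s$date, dates)
})

test_that("snow days per occasion count days at or above the threshold", {
  cal <- build_occasion_calendar("2009-12-01", 1)
  days <- cal$start_date[1] + 0:13
  expect_equal(snow_days_by_occasion(snow_series(days, rep(5, 14)), cal), 14L)
  expect_equal(snow_days_by_occasion(snow_series(days, rep(0, 14)), cal), 0L)
  depths <- c(2, 0, 1, rep(0, 11))
  expect_equal(snow_days_by_occasion(snow_series(days, depths), cal), 2L)
  expect_equal(snow_days_by_occasion(snow_series(days, depths), cal,
                                     depth_threshold = 2), 1L)
})

test_that("missing snow days follow the configured policy", {
  cal <- build_occasion_calendar("2009-12-01", 1)
  short <- snow_series(cal$start_date[1] + 0:9, rep(3, 10))
  expect_error(snow_days_by_occasion(short, cal), "strict")
  expect_warning(n <- snow_days_by_occasion(short, cal, missing = "zero"),
                 "snow-free")
  expect_equal(n, 10L)
})

test_that("raising the depth threshold never increases any count", {
  cal <- build_occasion_calendar("2009-11-01", 10)
  sz <- make_snow_z(cal, seed = 4)
  prev <- snow_days_by_occasion(sz$series, cal, depth_threshold = 0.5)
  for (thr in c(1, 2, 4, 8)) {
    cur <- snow_days_by_occasion(sz$series, cal, depth_threshold = thr)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("per-occasion counts conserve the total of qualifying days", {
  cal <- build_occasion_calendar("2009-11-01", 10)
  sz <- make_snow_z(cal, seed = 4)
  span <- sz$series$date >= cal$start_date[1] &
    sz$series$date <= cal$start_date[10] + 13
  expect_equal(sum(sz$snow_days),
               sum(sz$series$snow_cm[span] >= 1, na.rm = TRUE))
})

test_that("standardization is affine, invertible, and recorded", {
  z <- standardize_snow(c(0, 7, 14), center = 7, scale = 7)
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(as.numeric(standardize_snow(0:5, 0, 1)), 0:5)
  expect_equal(unstandardize_snow(z), c(0, 7, 14))
  expect_error(standardize_snow(1:3, 0, 0), "positive")

  # an explicit winter z-score yields mean 0, SD 1 over winter occasions
  cal <- make_calendar()
  sz <- make_snow_z(cal)
  w <- cal$season == "winter"
  zz <- standardize_snow(sz$snow_days, mean(sz$snow_days[w]),
                         sd(sz$snow_days[w]))
  expect_equal(mean(zz[w]), 0)
  expect_equal(sd(zz[w]), 1)

  # the default policy keeps z = 0 at zero snow days
  sc <- snow_standardization(sz$snow_days, cal)
  expect_equal(sc$center, 0)
  expect_equal(standardize_snow(0, sc$center, sc$scale)[1], 0)
})
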