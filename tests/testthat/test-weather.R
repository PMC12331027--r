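test_that("weather CSVs are read in day order and invalid rows are named", {
  path <- write_temp_csv(c("day,tmax,tmin,sr,rain",
                           "2,21,11,18,0", "1,20,10,17,2", "3,19,9,16,1"))
  w <- read_weather_csv(path)
  expect_s3_class(w, "daily_weather")
  expect_equal(w$day, 1:3)
  expect_equal(w$tmax, c(20, 21, 19))

  bad_order <- write_temp_csv(c("day,tmax,tmin,sr,rain", "1,10,15,18,0"))
  expect_error(read_weather_csv(bad_order), "tmax < tmin.*row 1")

  gap <- write_temp_csv(c("day,tmax,tmin,sr,rain",
                          "1,20,10,18,0", "2,20,10,18,0", "4,20,10,18,0"))
  expect_error(read_weather_csv(gap), "not contiguous")

  non_num <- write_temp_csv(c("day,tmax,tmin,sr,rain", "1,20,ten,18,0"))
  expect_error(read_weather_csv(non_num), "non-numeric.*tmin")

  no_col <- write_temp_csv(c("day,tmax,tmin,sr", "1,20,10,18"))
  expect_error(read_weather_csv(no_col), "missing column")
})

test_that("monthly disaggregation conserves rainfall and holds monthly values", {
  for (season in c("spring", "autumn", "early_spring")) {
    cl <- load_climate(season)
    for (dpm in c(30L, 31L)) {
      w <- disaggregate_monthly(cl, dpm)
      expect_equal(nrow(w), nrow(cl$months) * dpm)
      # per-month re-aggregation reproduces the monthly totals exactly
      month_of <- rep(seq_len(nrow(cl$months)), each = dpm)
      expect_equal(as.numeric(tapply(w$rain, month_of, sum)),
                   cl$months$rain, tolerance = 1e-12)
      expect_equal(as.numeric(tapply(w$tmax, month_of, mean)), cl$months$tmax)
      expect_equal(as.numeric(tapply(w$sr, month_of, mean)), cl$months$sr)
    }
  }
  one <- monthly_climate("one", data.frame(month = "m", tmax = 20, tmin = 10,
                                           rain = 31, sr = 15))
  expect_equal(unique(disaggregate_monthly(one, 31)$rain), 1)
  expect_error(disaggregate_monthly(list(), 30), "monthly_climate")
})

test_that("thermal time accumulates clamped degree-days from the origin", {
  w <- const_weather(10, tmax = 20, tmin = 10)
  tt <- thermal_time(w, base_temperature = 2)
  expect_equal(tt[1], 13)             # (20+10)/2 - 2
  expect_equal(tt[10], 130)
  expect_true(all(diff(tt) >= 0))

  cold <- const_weather(5, tmax = 3, tmin = -5)
  expect_equal(unname(thermal_time(cold, 2)[5]), 0)  # clamped at the base

  # days before the origin contribute nothing
  tt5 <- thermal_time(w, 2, origin_day = 5)
  expect_equal(tt5[4], 0)
  expect_equal(tt5[10], 6 * 13)

  expect_error(thermal_time(w, NaN), "finite")
  expect_error(thermal_time(w, 2, origin_day = 11), "outside")
})

test_that("thermal time is invariant under splitting and concatenation", {
  set.seed(11)
  n <- 40
  w <- daily_weather(1:n, tmax = runif(n, 10, 30), tmin = runif(n, 0, 10),
                     sr = runif(n, 5, 25), rain = runif(n, 0, 10))
  tt <- thermal_time(w, 2)
  for (cut in c(7L, 20L, 33L)) {
    a <- w[1:cut, ]; class(a) <- class(w)
    b <- w[(cut + 1):n, ]; b$day <- seq_len(n - cut); class(b) <- class(w)
    tt_a <- thermal_time(a, 2)
    tt_b <- thermal_time(b, 2)
    expect_equal(c(tt_a, tt_a[cut] + tt_b), as.numeric(tt),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("season summaries reproduce the bundled seasons' aggregates", {
  sp <- season_summary(load_climate("spring"))
  au <- season_summary(load_climate("autumn"))
  es <- season_summary(load_climate("early_spring"))

  expect_equal(sp$total_rain, 1149.2)
  expect_equal(au$total_rain, 362.4)
  expect_equal(es$total_rain, 190.1)

  expect_equal(round(au$mean_sr, 2), 11.74)
  expect_equal(round(es$mean_sr, 2), 19.13)

  # diurnal range computed as tmax - tmin per month
  expect_equal(au$tdif_range, c(7.8, 10.62))
  expect_equal(sp$tdif_range, c(6.9, 11.1), tolerance = 0.15)
  expect_equal(es$tdif_range[1], 12.4)

  one <- season_summary(monthly_climate("x", data.frame(
    month = "m", tmax = 20, tmin = 10, rain = 5, sr = 15)))
  expect_equal(one$tmax_range, c(20, 20))   # degenerate range
})
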