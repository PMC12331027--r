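#' Construct a validated daily-weather table
#'
#' A daily-weather table holds one row per day of a growing season with
#' maximum and minimum air temperature, total incident solar radiation and
#' rainfall. All downstream computations (thermal time, intercepted
#' radiation, the growth simulator) consume this container.
#'
#' @param day integer day index since the start of the season; must be
#'   contiguous (1, 2, 3, ...without gaps).
#' @param tmax,tmin daily maximum / minimum temperature (degrees C);
#'   `tmax >= tmin` row-wise.
#' @param sr daily total solar radiation (MJ m^-2 d^-1), non-negative.
#' @param rain daily rainfall (mm), non-negative.
#' @return a `data.frame` of class `"daily_weather"` with columns
#'   `day`, `tmax`, `tmin`, `sr`, `rain`.
#' @seealso [read_weather_csv()], [disaggregate_monthly()], [thermal_time()]
#' @export
#' @examples
#' w <- daily_weather(1:3, tmax = c(20, 21, 19), tmin = c(10, 9, 11),
#'                    sr = c(18, 17, 19), rain = c(0, 4, 0))
daily_weather <- function(day, tmax, tmin, sr, rain) {
  df <- data.frame(day = as.integer(day), tmax = as.numeric(tmax),
                   tmin = as.numeric(tmin), sr = as.numeric(sr),
                   rain = as.numeric(rain))
  validate_daily_weather(df)
}

validate_daily_weather <- function(df) {
  needed <- c("day", "tmax", "tmin", "sr", "rain")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_pg("weather table is missing column(s): %s",
            paste(missing, collapse = ", "))
  for (col in needed) {
    if (!is.numeric(df[[col]]))
      stop_pg("weather column '%s' is not numeric", col)
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop_pg("weather column '%s' has a non-finite value at row %d",
              col, bad[1L])
  }
  if (nrow(df) == 0L) stop_pg("weather table is empty")
  df <- df[order(df$day), , drop = FALSE]
  gaps <- which(diff(df$day) != 1L)
  if (length(gaps))
    stop_pg("weather days are not contiguous: day %d is followed by day %d (row %d)",
            df$day[gaps[1L]], df$day[gaps[1L] + 1L], gaps[1L] + 1L)
  bad <- which(df$tmax < df$tmin)
  if (length(bad))
    stop_pg("tmax < tmin at row %d (day %d: tmax = %g, tmin = %g)",
            bad[1L], df$day[bad[1L]], df$tmax[bad[1L]], df$tmin[bad[1L]])
  bad <- which(df$sr < 0)
  if (length(bad))
    stop_pg("negative solar radiation at row %d (day %d)", bad[1L], df$day[bad[1L]])
  bad <- which(df$rain < 0)
  if (length(bad))
    stop_pg("negative rainfall at row %d (day %d)", bad[1L], df$day[bad[1L]])
  rownames(df) <- NULL
  class(df) <- c("daily_weather", "data.frame")
  df
}

#' Read a daily-weather CSV
#'
#' Expects a header with columns `day,tmax,tmin,sr,rain` (UTF-8, `.`
#' decimal separator). Rows are validated (`tmax >= tmin`, non-negative
#' radiation and rainfall, contiguous days) and returned in day order.
#'
#' @param path path to the CSV file.
#' @return a [daily_weather()] table.
#' @export
read_weather_csv <- function(path) {
  if (!file.exists(path)) stop_pg("weather file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("day", "tmax", "tmin", "sr", "rain")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_pg("weather CSV '%s' is missing column(s): %s", path,
            paste(missing, collapse = ", "))
  for (col in needed) {
    v <- df[[col]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop_pg("non-numeric value '%s' in column '%s' at data row %d of %s",
                v[bad[1L]], col, bad[1L], path)
      df[[col]] <- vn
    }
  }
  validate_daily_weather(df[needed])
}

#' Construct a monthly climate summary for one cropping season
#'
#' Holds per-month mean maximum/minimum temperature, monthly total
#' rainfall, monthly mean daily solar radiation and (optionally) sunshine
#' hours. Months are ordinal positions within the season, not calendar
#' dates.
#'
#' @param season season label, e.g. `"spring"`, `"autumn"`,
#'   `"early_spring"` or any custom string.
#' @param months a `data.frame` with columns `month` (label), `tmax`,
#'   `tmin` (degrees C), `rain` (monthly total, mm), `sr` (monthly mean,
#'   MJ m^-2 d^-1) and optionally `snh` (sunshine hours).
#' @return an object of class `"monthly_climate"`.
#' @seealso [load_climate()] for the bundled seasonal tables,
#'   [disaggregate_monthly()], [season_summary()]
#' @export
monthly_climate <- function(season, months) {
  if (!is.character(season) || length(season) != 1L)
    stop_pg("'season' must be a single string")
  needed <- c("month", "tmax", "tmin", "rain", "sr")
  missing <- setdiff(needed, names(months))
  if (length(missing))
    stop_pg("monthly climate is missing column(s): %s",
            paste(missing, collapse = ", "))
  if (nrow(months) == 0L) stop_pg("monthly climate has no months")
  if (any(months$rain < 0)) stop_pg("monthly rainfall must be non-negative")
  if (any(months$tmax < months$tmin)) stop_pg("monthly tmax < tmin")
  if (any(months$sr < 0)) stop_pg("monthly solar radiation must be non-negative")
  structure(list(season = season,
                 months = as.data.frame(months, stringsAsFactors = FALSE)),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat(sprintf("Monthly climate: %s (%d months)\n", x$season, nrow(x$months)))
  print(x$months, row.names = FALSE)
  invisible(x)
}

#' Disaggregate a monthly climate into a daily-weather series
#'
#' Each day of a month carries that month's `tmax`, `tmin` and `sr`
#' unchanged; the monthly rainfall total is split uniformly across the
#' month's days, so re-summing the daily series per month reproduces the
#' monthly totals to machine precision. No within-month interpolation is
#' applied (the monthly tables carry no within-month structure).
#'
#' @param climate a [monthly_climate()] object.
#' @param days_per_month integer day count per month; a scalar is recycled
#'   across months (default 30).
#' @return a [daily_weather()] table with `sum(days_per_month)` rows.
#' @export
#' @examples
#' w <- disaggregate_monthly(load_climate("spring"), 30)
#' sum(w$rain)   # 1149.2, the seasonal total
disaggregate_monthly <- function(climate, days_per_month = 30L) {
  if (!inherits(climate, "monthly_climate"))
    stop_pg("'climate' must be a monthly_climate object")
  m <- climate$months
  nm <- nrow(m)
  if (nm == 0L) stop_pg("monthly climate has no months")
  days_per_month <- as.integer(rep_len(days_per_month, nm))
  if (any(days_per_month < 1L)) stop_pg("days_per_month must be >= 1")
  idx <- rep.int(seq_len(nm), days_per_month)
  daily_weather(day = seq_along(idx),
                tmax = m$tmax[idx],
                tmin = m$tmin[idx],
                sr = m$sr[idx],
                rain = m$rain[idx] / days_per_month[idx])
}

#' Cumulative thermal time (growing degree-days)
#'
#' Daily increment `max(0, (tmax + tmin)/2 - base_temperature)` (degree
#' C d), accumulated from `origin_day` onward; the origin day's own
#' increment is counted and days before the origin contribute 0. The
#' origin is conventionally the crop's emergence day.
#'
#' @param weather a [daily_weather()] table.
#' @param base_temperature base temperature (degrees C) below which no
#'   thermal time accrues; the potato convention of 2 degrees C is the
#'   default.
#' @param origin_day row index (1-based) at which the thermal-time clock
#'   starts.
#' @return a numeric vector of cumulative thermal time, one value per
#'   weather day, with attributes `base_temperature` and `origin_day`.
#' @export
#' @examples
#' w <- daily_weather(1:10, rep(20, 10), rep(10, 10), rep(18, 10), rep(0, 10))
#' thermal_time(w, base_temperature = 2)[10]   # 130 degree C d
thermal_time <- function(weather, base_temperature = 2, origin_day = 1L) {
  weather <- validate_daily_weather(as.data.frame(weather))
  check_number(base_temperature, "base_temperature")
  n <- nrow(weather)
  origin_day <- as.integer(origin_day)
  if (origin_day < 1L || origin_day > n)
    stop_pg("origin_day %d is outside the weather series (1..%d)", origin_day, n)
  inc <- pmax(0, (weather$tmax + weather$tmin) / 2 - base_temperature)
  inc[seq_len(origin_day - 1L)] <- 0
  tt <- cumsum(inc)
  attr(tt, "base_temperature") <- base_temperature
  attr(tt, "origin_day") <- origin_day
  tt
}

#' Seasonal aggregates of a monthly climate
#'
#' Computes the seasonal rainfall total, the unweighted mean of the
#' monthly solar-radiation means, and the (min, max) ranges of monthly
#' `tmax`, `tmin` and the diurnal range `tdif = tmax - tmin`.
#'
#' @param climate a [monthly_climate()] object.
#' @return a list of class `"season_summary"` with elements `season`,
#'   `n_months`, `total_rain` (mm), `mean_sr` (MJ m^-2 d^-1),
#'   `tmax_range`, `tmin_range`, `tdif_range` (degrees C, length-2
#'   vectors).
#' @export
#' @examples
#' season_summary(load_climate("autumn"))   # total rain 362.4, mean SR 11.74
season_summary <- function(climate) {
  if (!inherits(climate, "monthly_climate"))
    stop_pg("'climate' must be a monthly_climate object")
  m <- climate$months
  if (nrow(m) == 0L) stop_pg("monthly climate has no months")
  tdif <- m$tmax - m$tmin
  structure(list(season = climate$season,
                 n_months = nrow(m),
                 total_rain = sum(m$rain),
                 mean_sr = mean(m$sr),
                 tmax_range = range(m$tmax),
                 tmin_range = range(m$tmin),
                 tdif_range = range(tdif)),
            class = "season_summary")
}

#' @export
print.season_summary <- function(x, ...) {
  cat(sprintf("Season summary: %s (%d months)\n", x$season, x$n_months))
  cat(sprintf("  total rainfall : %.1f mm\n", x$total_rain))
  cat(sprintf("  mean radiation : %.2f MJ m-2 d-1\n", x$mean_sr))
  cat(sprintf("  Tmax range     : %.1f - %.1f C\n", x$tmax_range[1], x$tmax_range[2]))
  cat(sprintf("  Tmin range     : %.1f - %.1f C\n", x$tmin_range[1], x$tmin_range[2]))
  cat(sprintf("  Tdif range     : %.2f - %.2f C\n", x$tdif_range[1], x$tdif_range[2]))
  invisible(x)
}
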