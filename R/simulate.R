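#' Assemble a full crop-parameter set
#'
#' Bundles the canopy and partition curves with the radiation-use
#' efficiency and the conversion constants the simulator needs.
#'
#' The dry-matter fraction converts simulated tuber dry mass to fresh
#' yield and is not part of the fitted parameter vector; the default of
#' 0.20 is a typical tuber dry-matter content, and fresh yield scales as
#' its inverse, so set it from measurements whenever available.
#'
#' @param canopy a [canopy_parameters()] object.
#' @param partition a [partition_parameters()] object.
#' @param rue radiation-use efficiency (g dry biomass per MJ intercepted
#'   PAR), > 0.
#' @param dry_matter_fraction tuber dry-matter content as a fraction of
#'   fresh mass, in (0, 1); default 0.20.
#' @param base_temperature base temperature for thermal time (degrees C);
#'   default 2.
#' @return an object of class `"crop_parameters"`.
#' @export
crop_parameters <- function(canopy, partition, rue,
                            dry_matter_fraction = 0.20,
                            base_temperature = 2) {
  if (!inherits(canopy, "canopy_parameters"))
    stop_pg("'canopy' must be a canopy_parameters object")
  if (!inherits(partition, "partition_parameters"))
    stop_pg("'partition' must be a partition_parameters object")
  check_number(rue, "rue")
  if (rue < 0) stop_pg("rue = %g must be >= 0", rue)
  check_number(dry_matter_fraction, "dry_matter_fraction")
  if (dry_matter_fraction <= 0 || dry_matter_fraction >= 1)
    stop_pg("dry_matter_fraction = %g must be in (0, 1)", dry_matter_fraction)
  check_number(base_temperature, "base_temperature")
  structure(list(canopy = canopy, partition = partition, rue = rue,
                 dry_matter_fraction = dry_matter_fraction,
                 base_temperature = base_temperature),
            class = "crop_parameters")
}

#' @export
print.crop_parameters <- function(x, ...) {
  cat("Crop parameters\n")
  cat(sprintf("  canopy    : wmax %.4g, tm %.4g, te %.4g (degree C d)\n",
              x$canopy$wmax, x$canopy$tm, x$canopy$te))
  cat(sprintf("  partition : A %.4g, tu %.4g, b %.4g (degree C d)\n",
              x$partition$a_max, x$partition$tu, x$partition$b))
  cat(sprintf("  RUE %.4g g/MJ, dry-matter fraction %.3g, base temperature %g C\n",
              x$rue, x$dry_matter_fraction, x$base_temperature))
  invisible(x)
}

#' Photosynthetically active radiation from total solar radiation
#'
#' PAR is taken as 50% of total incident solar radiation.
#'
#' @param sr total solar radiation (MJ m^-2 d^-1), non-negative; vectorized.
#' @return PAR (MJ m^-2 d^-1).
#' @export
daily_par <- function(sr) {
  if (any(!is.finite(sr)) || any(sr < 0))
    stop_pg("'sr' must be finite and >= 0")
  0.5 * sr
}

#' Cumulative intercepted PAR
#'
#' Daily intercepted PAR is `par_fraction * sr * cover`; the cumulative
#' sum over days is the IPAR series against which biomass is regressed
#' and from which the simulator grows biomass. The PAR conversion is
#' applied exactly once (`par_fraction`, default 0.5).
#'
#' @param weather a [daily_weather()] table, or a numeric vector of daily
#'   solar radiation (MJ m^-2 d^-1).
#' @param cover_by_day canopy-cover fraction per day, same length as the
#'   weather series.
#' @param par_fraction fraction of solar radiation that is PAR (default 0.5).
#' @return nondecreasing numeric vector of cumulative IPAR (MJ m^-2).
#' @export
#' @examples
#' cumulative_ipar(rep(20, 10), rep(1, 10))[10]  # 100
cumulative_ipar <- function(weather, cover_by_day, par_fraction = 0.5) {
  sr <- if (is.numeric(weather)) weather else {
    validate_daily_weather(as.data.frame(weather))$sr
  }
  if (length(sr) != length(cover_by_day))
    stop_pg("weather series (%d days) and cover series (%d days) differ in length",
            length(sr), length(cover_by_day))
  if (any(!is.finite(cover_by_day)) || any(cover_by_day < 0 | cover_by_day > 1))
    stop_pg("cover values must lie in [0, 1]")
  check_number(par_fraction, "par_fraction", lower = 0, upper = 1)
  cumsum(par_fraction * sr * cover_by_day)
}

#' Harvest index from tuber and whole-plant dry mass
#'
#' @param tuber_dm tuber dry mass (g m^-2), `0 <= tuber_dm <= total_dm`.
#' @param total_dm whole-plant dry mass (g m^-2), > 0.
#' @return the ratio in \[0, 1\]; vectorized.
#' @export
#' @examples
#' harvest_index(82, 100)  # 0.82
harvest_index <- function(tuber_dm, total_dm) {
  if (any(!is.finite(tuber_dm)) || any(!is.finite(total_dm)))
    stop_pg("masses must be finite")
  if (any(total_dm <= 0)) stop_pg("total_dm must be > 0")
  if (any(tuber_dm < 0)) stop_pg("tuber_dm must be >= 0")
  if (any(tuber_dm > total_dm)) stop_pg("tuber_dm exceeds total_dm")
  tuber_dm / total_dm
}

#' Run the daily potential-growth simulation
#'
#' The radiation-driven daily loop under potential (non-limited)
#' conditions: from emergence, thermal time accumulates from the daily
#' mean temperature above the base temperature; canopy cover follows the
#' beta function of thermal time (held at `wmax` past `te`); daily
#' intercepted PAR is `par_fraction * sr * cover`; dry biomass grows by
#' `RUE` per MJ intercepted; tuber dry mass is the Gompertz harvest index
#' times cumulative biomass; fresh tuber yield at maturity is
#' `tuber_dm / dry_matter_fraction * 0.01` (g m^-2 to t ha^-1).
#'
#' An optional senescence onset day makes cover decline linearly from its
#' current value at `senescence_day` to zero at `maturity_day` (use the
#' observed date of 50% death above ground when available); by default no
#' decline is applied before harvest.
#'
#' @param weather a [daily_weather()] table covering the season.
#' @param params a [crop_parameters()] object.
#' @param emergence_day day index of 50% emergence (thermal-time origin).
#' @param maturity_day day index of physiological maturity / harvest;
#'   `emergence_day <= maturity_day <= nrow(weather)`.
#' @param senescence_day optional day index at which canopy decline
#'   begins.
#' @param par_fraction PAR fraction of solar radiation (default 0.5).
#' @return an object of class `"potato_sim"`: a list with `trajectory`
#'   (data frame of day, tt, cover, ipar, cum_ipar, biomass,
#'   harvest_index, tuber_dm), `fresh_yield` (t ha^-1), and the inputs.
#' @seealso [potential_yield()] for the monthly-climate convenience
#'   wrapper.
#' @export
simulate_growth <- function(weather, params, emergence_day, maturity_day,
                            senescence_day = NULL, par_fraction = 0.5) {
  weather <- validate_daily_weather(as.data.frame(weather))
  if (!inherits(params, "crop_parameters"))
    stop_pg("'params' must be a crop_parameters object")
  n <- nrow(weather)
  emergence_day <- as.integer(emergence_day)
  maturity_day <- as.integer(maturity_day)
  if (emergence_day < 1L || emergence_day > maturity_day || maturity_day > n)
    stop_pg("need 1 <= emergence_day <= maturity_day <= %d (got %d, %d)",
            n, emergence_day, maturity_day)
  tt <- thermal_time(weather, params$base_temperature, emergence_day)
  days <- seq_len(maturity_day)
  tt <- tt[days]
  cover <- beta_canopy(tt, params$canopy)
  cover[seq_len(emergence_day - 1L)] <- 0
  if (!is.null(senescence_day)) {
    senescence_day <- as.integer(senescence_day)
    if (senescence_day < emergence_day || senescence_day > maturity_day)
      stop_pg("senescence_day must lie in [emergence_day, maturity_day]")
    if (senescence_day < maturity_day) {
      fade <- pmax(0, (maturity_day - days) / (maturity_day - senescence_day))
      cover <- cover * pmin(1, fade)
    }
  }
  ipar_daily <- par_fraction * weather$sr[days] * cover
  cum_ipar <- cumsum(ipar_daily)
  biomass <- params$rue * cum_ipar
  hi <- gompertz_partition(tt, params$partition)
  tuber_dm <- hi * biomass
  fresh_yield <- tuber_dm[maturity_day] / params$dry_matter_fraction * 0.01
  structure(list(
    trajectory = data.frame(day = days, tt = as.numeric(tt), cover = cover,
                            ipar = ipar_daily, cum_ipar = cum_ipar,
                            biomass = biomass, harvest_index = hi,
                            tuber_dm = tuber_dm),
    fresh_yield = fresh_yield,
    params = params, emergence_day = emergence_day,
    maturity_day = maturity_day, senescence_day = senescence_day,
    par_fraction = par_fraction),
    class = "potato_sim")
}

#' Potential fresh tuber yield from a monthly climate
#'
#' Convenience wrapper: disaggregates the monthly climate to a daily
#' series ([disaggregate_monthly()]), runs [simulate_growth()] and
#' returns the final fresh tuber yield.
#'
#' @param params a [crop_parameters()] object.
#' @param climate a [monthly_climate()] object.
#' @param emergence_day,maturity_day phenology (day indices into the
#'   disaggregated season); `maturity_day` defaults to the season's last
#'   day.
#' @param days_per_month day count per month for disaggregation.
#' @param ... passed to [simulate_growth()] (e.g. `senescence_day`).
#' @return potential fresh tuber yield (t ha^-1).
#' @export
#' @examples
#' p <- crop_parameter_set("Yunshu 505", "spring")
#' potential_yield(p, load_climate("spring"),
#'                 emergence_day = 44, maturity_day = 164)
potential_yield <- function(params, climate, emergence_day,
                            maturity_day = NULL, days_per_month = 30L, ...) {
  weather <- disaggregate_monthly(climate, days_per_month)
  maturity_day <- maturity_day %||% nrow(weather)
  simulate_growth(weather, params, emergence_day, maturity_day, ...)$fresh_yield
}

#' @export
print.potato_sim <- function(x, ...) {
  tr <- x$trajectory
  last <- tr[nrow(tr), ]
  cat("Potential-growth simulation\n")
  cat(sprintf("  emergence day %d, maturity day %d (%d simulated days)\n",
              x$emergence_day, x$maturity_day, nrow(tr)))
  cat(sprintf("  thermal time at maturity : %.0f degree C d\n", last$tt))
  cat(sprintf("  peak canopy cover        : %.3f\n", max(tr$cover)))
  cat(sprintf("  cumulative IPAR          : %.1f MJ m-2\n", last$cum_ipar))
  cat(sprintf("  final dry biomass        : %.0f g m-2\n", last$biomass))
  cat(sprintf("  final harvest index      : %.3f\n", last$harvest_index))
  cat(sprintf("  fresh tuber yield        : %.1f t/ha\n", x$fresh_yield))
  invisible(x)
}

#' @export
summary.potato_sim <- function(object, ...) print(object, ...)

#' @export
as.data.frame.potato_sim <- function(x, ...) x$trajectory

#' @export
plot.potato_sim <- function(x, ...) {
  tr <- x$trajectory
  op <- par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(tr$day, tr$cover, type = "l", xlab = "day", ylab = "canopy cover",
       main = "Canopy", ...)
  plot(tr$day, tr$biomass, type = "l", xlab = "day",
       ylab = "dry biomass (g/m2)", main = "Biomass")
  lines(tr$day, tr$tuber_dm, lty = 2)
  legend("topleft", c("total", "tuber"), lty = 1:2, bty = "n")
  plot(tr$day, tr$harvest_index, type = "l", xlab = "day",
       ylab = "harvest index", main = "Partitioning")
  invisible(x)
}
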