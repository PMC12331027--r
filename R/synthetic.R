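## Seeded synthetic-data generator: emulates one season's field trial
## (daily weather, canopy imaging, destructive biomass sampling, repeated
## harvests, late-blight scoring) with known ground truth, so every
## estimation and simulation stage can be tested end to end.

#' Configuration for the synthetic-trial generator
#'
#' Defaults emulate an autumn-season trial: the bundled autumn monthly
#' climate, a representative truth parameter set (wmax 0.92, tm 449, te
#' 1027 degree C d; A 0.97, tu 545, b 186 degree C d; RUE 3.13 g/MJ),
#' canopy-image noise sd 0.02 (absolute, on a fraction), biomass sampling
#' CV 5% (multiplicative log-normal, destructive sampling), harvest-index
#' reading sd 0.03, severity reading sd 3 percentage points, and observations every 10 days.
#'
#' @param seed integer seed; identical configurations generate identical
#'   data.
#' @param season a season label understood by [load_climate()] or a
#'   custom [monthly_climate()] object.
#' @param truth the generating [crop_parameters()]; `NULL` for the
#'   default set above.
#' @param canopy_sd additive Gaussian sd of canopy-cover observations.
#' @param biomass_cv coefficient of variation of the multiplicative
#'   log-normal plot-level biomass sampling noise.
#' @param hi_sd additive Gaussian sd of harvest-index (partition
#'   fraction) readings, truncated to \[0, 1\].
#' @param severity_sd Gaussian sd of severity readings (percentage
#'   points).
#' @param cadence observation interval in days.
#' @param n_reps replicate observations per sampling date (the emulated
#'   trial is a randomized complete block design with three
#'   replications).
#' @param days_per_month days per month for climate disaggregation.
#' @param temp_jitter_sd,sr_jitter_sd day-to-day Gaussian jitter of the
#'   daily mean temperature (degrees C) and solar radiation (MJ m^-2
#'   d^-1); deviations are re-centred within each month, so monthly
#'   aggregates are conserved exactly at any jitter level.
#' @param emergence_day,maturity_day phenology; `maturity_day` defaults
#'   to the last season day.
#' @param epidemic_onset_frac position of the uncontrolled epidemic's
#'   50%-severity day as a fraction of the emergence-maturity span.
#' @param epidemic_rate logistic rate of the epidemic (d^-1).
#' @param control_efficacy fraction of severity suppressed by fungicide
#'   protection in the controlled treatment.
#' @return a list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L, season = "autumn", truth = NULL,
                             canopy_sd = 0.02, biomass_cv = 0.05,
                             hi_sd = 0.03, severity_sd = 3, cadence = 10L,
                             n_reps = 3L, days_per_month = 30L,
                             temp_jitter_sd = 1.5, sr_jitter_sd = 2,
                             emergence_day = 20L, maturity_day = NULL,
                             epidemic_onset_frac = 0.6,
                             epidemic_rate = 0.15,
                             control_efficacy = 0.97) {
  truth <- truth %||% crop_parameters(
    canopy = canopy_parameters(0.92, 449, 1027),
    partition = partition_parameters(0.97, 545, 186),
    rue = 3.13)
  if (!inherits(truth, "crop_parameters"))
    stop_pg("'truth' must be a crop_parameters object")
  for (nm in c("canopy_sd", "biomass_cv", "hi_sd", "severity_sd"))
    check_number(get(nm), nm, lower = 0)
  check_number(epidemic_onset_frac, "epidemic_onset_frac", 0, 1)
  check_number(control_efficacy, "control_efficacy", 0, 1)
  structure(list(seed = as.integer(seed), season = season, truth = truth,
                 canopy_sd = canopy_sd, biomass_cv = biomass_cv,
                 hi_sd = hi_sd, severity_sd = severity_sd, cadence = as.integer(cadence),
                 n_reps = max(1L, as.integer(n_reps)),
                 days_per_month = as.integer(days_per_month),
                 temp_jitter_sd = temp_jitter_sd, sr_jitter_sd = sr_jitter_sd,
                 emergence_day = as.integer(emergence_day),
                 maturity_day = maturity_day,
                 epidemic_onset_frac = epidemic_onset_frac,
                 epidemic_rate = epidemic_rate,
                 control_efficacy = control_efficacy),
            class = "synthetic_config")
}

.config_climate <- function(config) {
  if (inherits(config$season, "monthly_climate")) config$season
  else load_climate(config$season)
}

#' Generate a daily-weather series from a monthly climate template
#'
#' Starts from [disaggregate_monthly()] and, when jitter is configured,
#' adds day-to-day variation: the daily mean temperature and solar
#' radiation receive Gaussian deviations that are re-centred within each
#' month (the monthly diurnal range is kept, so `tmax >= tmin` always
#' holds), and monthly rainfall is split across days with Gamma-weighted
#' shares (a few wet days, many near-dry ones). Monthly means of
#' temperature and radiation and monthly rainfall totals are conserved
#' exactly; with both jitter sds at 0 the plain disaggregation is
#' returned.
#'
#' Calls [set.seed()] with the configured seed.
#'
#' @param config a [synthetic_config()].
#' @return a [daily_weather()] table.
#' @export
generate_weather <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop_pg("'config' must be a synthetic_config object")
  set.seed(config$seed)
  climate <- .config_climate(config)
  base <- disaggregate_monthly(climate, config$days_per_month)
  if (config$temp_jitter_sd == 0 && config$sr_jitter_sd == 0) return(base)
  nm <- nrow(climate$months)
  counts <- rep_len(config$days_per_month, nm)
  month_of <- rep.int(seq_len(nm), counts)
  out <- as.data.frame(base)
  for (m in seq_len(nm)) {
    i <- which(month_of == m)
    n <- length(i)
    dev_t <- rnorm(n, 0, config$temp_jitter_sd)
    dev_t <- dev_t - mean(dev_t)
    half_range <- (out$tmax[i] - out$tmin[i]) / 2
    tmean <- (out$tmax[i] + out$tmin[i]) / 2 + dev_t
    out$tmax[i] <- tmean + half_range
    out$tmin[i] <- tmean - half_range
    dev_s <- rnorm(n, 0, config$sr_jitter_sd)
    dev_s <- dev_s - mean(dev_s)
    out$sr[i] <- pmax(0, out$sr[i] + dev_s)
    w <- rgamma(n, shape = 0.3, rate = 1)
    if (sum(w) <= 0) w <- rep(1, n)
    out$rain[i] <- sum(out$rain[i]) * w / sum(w)
  }
  validate_daily_weather(out)
}

#' Generate one complete synthetic field trial
#'
#' Produces every observation series the analysis chain consumes,
#' together with the generating truth: (a) a daily weather series; (b) a
#' canopy-cover series following the beta function of thermal time plus
#' truncated Gaussian noise; (c) a destructive biomass-sampling series
#' (total and tuber dry mass) that is `RUE x cumulative IPAR` times
#' multiplicative log-normal noise; (d) the derived harvest-index series;
#' (e) cumulative tuber-yield curves and seven-reading late-blight
#' severity assessments for a fungicide-protected (`controlled`) and an
#' inoculated (`uncontrolled`) treatment. The uncontrolled epidemic is a
#' logistic severity curve that removes the diseased canopy fraction from
#' radiation interception — the epidemic terminates the growth cycle
#' early — so the uncontrolled yield curve flattens below the controlled
#' one.
#'
#' Calls [set.seed()] with the configured seed; identical configurations
#' give identical trials.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `"synthetic_trial"` with elements `weather`,
#'   `canopy` (day, tt, cover), `biomass` (day, total_dm, tuber_dm),
#'   `hi` (day, tt, hi), `ipar_cumulative`, `yield_controlled`,
#'   `yield_uncontrolled` ([yield_curve()]s), `disease_controlled`,
#'   `disease_uncontrolled` ([disease_assessment()]s), `truth` (the
#'   generating parameters, phenology and epidemic settings) and
#'   `config`.
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop_pg("'config' must be a synthetic_config object")
  weather <- generate_weather(config)   # seeds the RNG stream
  p <- config$truth
  em <- config$emergence_day
  mat <- config$maturity_day %||% nrow(weather)
  if (em < 1L || em >= mat || mat > nrow(weather))
    stop_pg("phenology (emergence %d, maturity %d) is outside the %d-day season",
            em, mat, nrow(weather))
  sim <- simulate_growth(weather, p, em, mat)
  tr <- sim$trajectory
  dates <- seq.int(em, mat, by = config$cadence)
  obs_days <- rep(dates, each = config$n_reps)   # one row per replicate plot
  n_obs <- length(obs_days)

  canopy <- data.frame(
    day = obs_days, tt = tr$tt[obs_days],
    cover = pmin(1, pmax(0, tr$cover[obs_days] +
                              rnorm(n_obs, 0, config$canopy_sd))))

  # destructive sampling: one multiplicative plot-level factor on total dry
  # mass; the measured partition fraction carries its own additive reading
  # error, and tuber mass is partition x total so the tables stay consistent
  sdlog <- sqrt(log(1 + config$biomass_cv^2))
  noise1 <- exp(rnorm(n_obs, -sdlog^2 / 2, sdlog))
  total_dm <- tr$biomass[obs_days] * noise1
  hi_obs <- pmin(1, pmax(0, tr$harvest_index[obs_days] +
                              rnorm(n_obs, 0, config$hi_sd)))
  tuber_dm <- hi_obs * total_dm
  biomass <- data.frame(day = obs_days, total_dm = total_dm,
                        tuber_dm = tuber_dm)
  hi <- data.frame(day = obs_days, tt = tr$tt[obs_days], hi = hi_obs)

  # late-blight epidemic: logistic severity; the diseased canopy fraction
  # stops intercepting radiation
  t50_epi <- em + config$epidemic_onset_frac * (mat - em)
  days <- tr$day
  sev_u <- logistic_raw(days, 100, config$epidemic_rate, t50_epi)
  sev_c <- (1 - config$control_efficacy) * sev_u
  yield_from_cover <- function(sev) {
    cover <- tr$cover * (1 - sev / 100)
    cum_ipar <- cumulative_ipar(weather$sr[days], cover, sim$par_fraction)
    tuber <- tr$harvest_index * p$rue * cum_ipar
    tuber / p$dry_matter_fraction * 0.01
  }
  y_c <- yield_from_cover(sev_c)
  y_u <- yield_from_cover(sev_u)
  yield_controlled <- yield_curve("synthetic", "controlled",
                                  dates, y_c[dates])
  yield_uncontrolled <- yield_curve("synthetic", "uncontrolled",
                                    dates, y_u[dates])

  read_days <- round(seq(em, mat, length.out = 7L))
  noisy_sev <- function(s) pmin(100, pmax(0, s[read_days] +
                                            rnorm(7L, 0, config$severity_sd)))
  disease_uncontrolled <- disease_assessment("synthetic", "uncontrolled",
                                             read_days, noisy_sev(sev_u))
  disease_controlled <- disease_assessment("synthetic", "controlled",
                                           read_days, noisy_sev(sev_c))

  structure(list(weather = weather, canopy = canopy, biomass = biomass,
                 hi = hi, ipar_cumulative = tr$cum_ipar,
                 yield_controlled = yield_controlled,
                 yield_uncontrolled = yield_uncontrolled,
                 disease_controlled = disease_controlled,
                 disease_uncontrolled = disease_uncontrolled,
                 truth = list(params = p, emergence_day = em,
                              maturity_day = mat, epidemic_t50 = t50_epi,
                              epidemic_rate = config$epidemic_rate,
                              final_yield_controlled = y_c[mat],
                              final_yield_uncontrolled = y_u[mat]),
                 config = config),
            class = "synthetic_trial")
}

#' Parameter-recovery experiment over seeded replicate trials
#'
#' Generates `n_seeds` synthetic trials (seeds `config$seed`,
#' `config$seed + 1`, ...), refits the seven model parameters from each
#' (beta canopy fit, Gompertz harvest-index fit, RUE regression) and
#' returns the relative errors against the generating truth — the
#' package's standard check that the estimation chain recovers known
#' parameters at the documented noise levels.
#'
#' @param config a [synthetic_config()]; its seed is the first replicate
#'   seed.
#' @param n_seeds number of replicate trials.
#' @return a `data.frame` with one row per replicate and columns `seed`
#'   plus the relative error (|estimate - truth| / |truth|) of `wmax`,
#'   `tm`, `te`, `a_max`, `tu`, `b` and `rue`.
#' @export
#' @examples
#' rec <- parameter_recovery(synthetic_config(seed = 42), n_seeds = 3)
#' apply(rec[-1], 2, median)
parameter_recovery <- function(config, n_seeds = 20L) {
  truth <- config$truth
  true_vec <- c(wmax = truth$canopy$wmax, tm = truth$canopy$tm,
                te = truth$canopy$te, a_max = truth$partition$a_max,
                tu = truth$partition$tu, b = truth$partition$b,
                rue = truth$rue)
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    trial <- generate_trial(cfg)
    fb <- fit_beta_canopy(trial$canopy[, c("tt", "cover")])
    fg <- fit_gompertz_hi(trial$hi[, c("tt", "hi")])
    fr <- estimate_rue(trial$biomass, trial$ipar_cumulative)
    est <- c(wmax = unname(coef(fb)[["wmax"]]), tm = unname(coef(fb)[["tm"]]),
             te = unname(coef(fb)[["te"]]), a_max = unname(coef(fg)[["a_max"]]),
             tu = unname(coef(fg)[["tu"]]), b = unname(coef(fg)[["b"]]),
             rue = fr$rue)
    data.frame(seed = cfg$seed,
               as.list(abs(est - true_vec) / abs(true_vec)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
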