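# constant-weather helper: n identical days
const_weather <- function(n, tmax = 20, tmin = 10, sr = 20, rain = 0) {
  daily_weather(seq_len(n), rep(tmax, n), rep(tmin, n), rep(sr, n), rep(rain, n))
}

# dense noise-free canopy / harvest-index series from known truth
canopy_series_from <- function(p, tt) data.frame(tt = tt, cover = beta_canopy(tt, p))
hi_series_from <- function(p, tt) data.frame(tt = tt, hi = gompertz_partition(tt, p))

# the nine bundled cultivar-season parameter rows
all_parameter_rows <- function() load_parameter_sets()

write_temp_csv <- function(text) {
  path <- tempfile(fileext = ".csv")
  writeLines(text, path)
  path
}
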