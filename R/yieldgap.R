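#' Season-by-genotype yield records
#'
#' The container for yield-gap accounting: one row per season and
#' genotype with the simulated potential yield and, when known, the
#' season's actual farm yield.
#'
#' @param season character vector of season labels.
#' @param genotype character vector of genotype labels.
#' @param potential potential yields (t ha^-1), >= 0.
#' @param actual actual farm yields (t ha^-1), >= 0 or `NA` when unknown.
#' @return a `data.frame` of class `"season_yield_records"`.
#' @seealso [reference_yield_records()] for the bundled three-season data.
#' @export
season_yield_records <- function(season, genotype, potential, actual = NA_real_) {
  df <- data.frame(season = as.character(season),
                   genotype = as.character(genotype),
                   potential = as.numeric(potential),
                   actual = as.numeric(actual))
  if (nrow(df) == 0L) stop_pg("no yield records supplied")
  if (any(df$potential < 0, na.rm = TRUE) || any(df$actual < 0, na.rm = TRUE))
    stop_pg("yields must be non-negative")
  class(df) <- c("season_yield_records", "data.frame")
  df
}

#' Seasonal mean potential yield
#'
#' Unweighted mean of the potential yields across the genotypes recorded
#' for one season.
#'
#' @param records a [season_yield_records()] table.
#' @param season the season label to average.
#' @return mean potential yield (t ha^-1).
#' @export
#' @examples
#' seasonal_mean_potential(reference_yield_records(), "spring")  # 125.63
seasonal_mean_potential <- function(records, season) {
  pot <- records$potential[records$season == season]
  if (!length(pot)) stop_pg("no records for season '%s'", season)
  mean(pot)
}

#' Yield gap
#'
#' The difference between potential and actual yield. A negative gap
#' (actual above potential) is allowed but flagged with a warning.
#'
#' @param potential,actual yields (t ha^-1), >= 0; vectorized.
#' @return `potential - actual` (t ha^-1).
#' @export
#' @examples
#' yield_gap(125.6, 19.6)  # 106
yield_gap <- function(potential, actual) {
  if (any(potential < 0) || any(actual < 0))
    stop_pg("yields must be non-negative")
  gap <- potential - actual
  if (any(gap < 0))
    warning("actual yield exceeds potential yield: negative gap", call. = FALSE)
  gap
}

#' Per-season yield-gap report
#'
#' One row per season with the mean potential yield across genotypes, the
#' actual farm yield, the yield gap and the relative gap. To keep the
#' arithmetic consistent with values reported at fixed precision, the
#' seasonal mean potential is rounded to `digits` decimals before the gap
#' is taken (set `digits = Inf` to difference unrounded means).
#'
#' @param records a [season_yield_records()] table; rows with `NA` actual
#'   yield contribute to the mean potential but the season's actual/gap
#'   columns are `NA` unless some row carries an actual yield.
#' @param digits decimals the mean potential is rounded to before
#'   differencing (default 1).
#' @return a `data.frame` with columns `season`, `n_genotypes`,
#'   `mean_potential`, `actual`, `gap`, `relative_gap_pct`.
#' @export
#' @examples
#' gap_report(reference_yield_records())
gap_report <- function(records, digits = 1) {
  if (nrow(records) == 0L) stop_pg("no yield records supplied")
  seasons <- unique(records$season)
  rows <- lapply(seasons, function(s) {
    sub <- records[records$season == s, , drop = FALSE]
    mp <- mean(sub$potential)
    mp_r <- if (is.finite(digits)) round(mp, digits) else mp
    act <- if (all(is.na(sub$actual))) NA_real_ else mean(sub$actual, na.rm = TRUE)
    gap <- if (is.na(act)) NA_real_ else yield_gap(mp_r, act)
    data.frame(season = s, n_genotypes = nrow(sub), mean_potential = mp_r,
               actual = act, gap = gap,
               relative_gap_pct = if (is.na(gap)) NA_real_ else 100 * gap / mp_r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
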