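#' Late-blight severity assessment series
#'
#' Repeated visual readings of the percentage of foliage affected for one
#' genotype under one treatment. The time axis may be Julian days, days
#' after planting or days after emergence — only differences between
#' reading times enter the AUDPC.
#'
#' @param genotype genotype label.
#' @param treatment `"controlled"` (fungicide-protected) or
#'   `"uncontrolled"`.
#' @param day reading times (days), strictly increasing.
#' @param severity percentage of foliage affected, in \[0, 100\].
#' @return a `data.frame` of class `"disease_assessment"` with attributes
#'   `genotype` and `treatment`.
#' @export
disease_assessment <- function(genotype, treatment, day, severity) {
  treatment <- match.arg(treatment, c("controlled", "uncontrolled"))
  if (length(day) != length(severity))
    stop_pg("'day' and 'severity' differ in length")
  if (any(!is.finite(day)) || any(!is.finite(severity)))
    stop_pg("readings must be finite")
  if (any(diff(day) <= 0))
    stop_pg("reading times must be strictly increasing")
  if (any(severity < 0 | severity > 100))
    stop_pg("severity must lie in [0, 100] percent")
  structure(data.frame(day = as.numeric(day), severity = as.numeric(severity)),
            genotype = as.character(genotype), treatment = treatment,
            class = c("disease_assessment", "data.frame"))
}

#' Area under the disease-progress curve (AUDPC)
#'
#' The midpoint formula over consecutive reading pairs:
#' \deqn{AUDPC = \sum_{i=1}^{n-1} \frac{y_i + y_{i+1}}{2} (t_{i+1} - t_i)}
#' with `y` the severity percentage at reading time `t` — percent-days of
#' disease pressure.
#'
#' @param x a [disease_assessment()] (or any data frame with `day` and
#'   `severity` columns), or a numeric vector of reading times when
#'   `severity` is supplied separately.
#' @param severity severity readings when `x` is the time vector.
#' @return the AUDPC (percent-days), >= 0.
#' @export
#' @examples
#' audpc(c(0, 10, 20), c(0, 10, 30))  # 250
audpc <- function(x, severity = NULL) {
  if (is.numeric(x) && !is.null(severity)) {
    if (length(x) != length(severity))
      stop_pg("'x' and 'severity' differ in length")
    d <- data.frame(day = x, severity = severity)
  } else if (is.data.frame(x)) {
    if (!all(c("day", "severity") %in% names(x)))
      stop_pg("'x' needs 'day' and 'severity' columns")
    d <- x
  } else stop_pg("'x' must be a disease assessment or a time vector")
  if (nrow(d) < 2L)
    stop_pg("AUDPC needs at least 2 readings (got %d)", nrow(d))
  if (any(diff(d$day) <= 0))
    stop_pg("reading times must be strictly increasing")
  if (any(d$severity < 0 | d$severity > 100))
    stop_pg("severity must lie in [0, 100] percent")
  n <- nrow(d)
  sum((d$severity[-n] + d$severity[-1L]) / 2 * diff(d$day))
}

#' Normalize an AUDPC to a unit-scaled disease index
#'
#' Divides the AUDPC by (time span x 100), the area of the worst-case
#' epidemic (100% severity throughout), giving an index in \[0, 1\] that
#' is comparable across assessment windows.
#'
#' @param assessment a [disease_assessment()] or compatible data frame.
#' @return the relative AUDPC in \[0, 1\].
#' @export
disease_index <- function(assessment) {
  a <- audpc(assessment)
  span <- diff(range(assessment$day))
  a / (span * 100)
}

#' Regression of tuber yield on disease index
#'
#' Ordinary least squares of yield on a per-plot disease index (e.g. the
#' normalized AUDPC from [disease_index()]). Late blight shortens the
#' effective growing period, so the expected slope is negative; a
#' positive fitted slope is reported with a warning.
#'
#' @param pairs a data frame with columns `index` (or `disease_index`)
#'   and `yield`; at least 3 pairs.
#' @return a list of class `"dy_regression"`: `slope`, `intercept`,
#'   `r_squared`, `n` and the underlying `lm` fit.
#' @export
#' @examples
#' idx <- c(0.1, 0.4, 0.8)
#' disease_yield_regression(data.frame(index = idx, yield = -2351 * idx + 3553))
disease_yield_regression <- function(pairs) {
  d <- .as_xy_series(pairs, c("index", "disease_index", "x"),
                     c("yield", "y"), "pairs")
  if (nrow(d) < 3L) stop_pg("need at least 3 pairs (got %d)", nrow(d))
  if (var(d$x) < .Machine$double.eps)
    stop_pg("disease index has zero variance")
  fit <- lm(y ~ x, data = d)
  r2 <- if (var(d$y) < .Machine$double.eps) 0 else
    suppressWarnings(summary(fit))$r.squared   # quiet on exact fits
  slope <- unname(coef(fit)[["x"]])
  if (slope > 0)
    warning("positive disease-yield slope: more disease associated with more yield",
            call. = FALSE)
  structure(list(slope = slope, intercept = unname(coef(fit)[[1L]]),
                 r_squared = r2, n = nrow(d), fit = fit),
            class = "dy_regression")
}

#' @export
print.dy_regression <- function(x, ...) {
  cat(sprintf("yield = %.4g x index + %.4g   (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Cumulative tuber-yield curve
#'
#' Repeated harvests of cumulative tuber yield over the season for one
#' genotype under one treatment, the input to [fit_logistic_curve()].
#'
#' @param genotype genotype label.
#' @param treatment `"controlled"` or `"uncontrolled"`.
#' @param day harvest days, increasing.
#' @param yield cumulative tuber yield (t ha^-1 or any consistent unit),
#'   >= 0.
#' @return a `data.frame` of class `"yield_curve"` with attributes
#'   `genotype` and `treatment`.
#' @export
yield_curve <- function(genotype, treatment, day, yield) {
  treatment <- match.arg(treatment, c("controlled", "uncontrolled"))
  if (length(day) != length(yield)) stop_pg("'day' and 'yield' differ in length")
  if (any(diff(day) <= 0)) stop_pg("harvest days must be strictly increasing")
  if (any(yield < 0)) stop_pg("yields must be non-negative")
  structure(data.frame(day = as.numeric(day), yield = as.numeric(yield)),
            genotype = as.character(genotype), treatment = treatment,
            class = c("yield_curve", "data.frame"))
}

# final yield of a curve or logistic fit: the fitted asymptote when a fit
# converged, the last observed point otherwise
.final_yield <- function(x) {
  if (inherits(x, "growth_fit")) {
    if (x$converged) return(x$coefficients[["k"]])
    return(max(x$data$y))
  }
  if (max(x$yield) <= 0) return(0)
  fit <- tryCatch(fit_logistic_curve(x), error = function(e) NULL)
  if (!is.null(fit) && fit$converged) fit$coefficients[["k"]]
  else x$yield[nrow(x)]
}

#' Yield increase from disease control
#'
#' The percentage increase of final tuber yield in the
#' fungicide-protected treatment over the unprotected one:
#' `(controlled - uncontrolled) / uncontrolled * 100`. Final yields are
#' the logistic asymptotes when fits converge, otherwise the last
#' observed points.
#'
#' @param controlled,uncontrolled [yield_curve()] objects or converged
#'   logistic `"growth_fit"`s.
#' @return the yield increase (%).
#' @export
#' @examples
#' yc <- yield_curve("A", "controlled", c(10, 30, 50), c(5, 20, 43))
#' yu <- yield_curve("A", "uncontrolled", c(10, 30, 50), c(4, 12, 20))
#' yield_increase_percent(yc, yu)   # (43 - 20)/20 * 100 = 115
yield_increase_percent <- function(controlled, uncontrolled) {
  fc <- .final_yield(controlled)
  fu <- .final_yield(uncontrolled)
  if (fu <= 0) stop_pg("uncontrolled final yield is zero: increase undefined")
  (fc - fu) / fu * 100
}

#' Shift of the maximum tuberization-rate day under disease control
#'
#' Both curves are fitted with [fit_logistic_curve()] (or converged fits
#' are supplied directly); the shift is `t50(controlled) -
#' t50(uncontrolled)` in days — positive when protection delays the
#' fastest tuber bulking, i.e. extends the growth period.
#'
#' @param controlled,uncontrolled [yield_curve()] objects or logistic
#'   `"growth_fit"`s.
#' @return the shift in days.
#' @export
max_rate_shift_days <- function(controlled, uncontrolled) {
  get_t50 <- function(x, label) {
    fit <- if (inherits(x, "growth_fit")) x else fit_logistic_curve(x)
    if (!fit$converged)
      stop_pg("logistic fit for the %s curve did not converge", label)
    fit$coefficients[["t50"]]
  }
  get_t50(controlled, "controlled") - get_t50(uncontrolled, "uncontrolled")
}
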