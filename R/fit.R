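## Nonlinear least-squares fitters for the canopy, harvest-index and
## tuberization curves. All return a classed "growth_fit" object with the
## usual modelling methods (print, summary, coef, predict, fitted,
## residuals, plot, simulate).

# Solver settings: Levenberg-Marquardt via minpack.lm, parameter tolerance
# 1e-10, up to 500 iterations; when the data-driven start fails, 5 jittered
# restarts (deterministic jitter) and the lowest-RSS convergent fit wins.
.fit_control <- function() minpack.lm::nls.lm.control(
  maxiter = 500L, ptol = 1e-10, ftol = 1e-10)

.jitter_factors <- function(n_par, n_starts = 5L) {
  # fixed low-discrepancy jitter grid: deterministic, no RNG state touched
  base <- c(0.8, 1.25, 0.6, 1.6, 0.95)
  outer(base[seq_len(n_starts)], seq_len(n_par)^0 ) *
    matrix(rep(c(1, 0.9, 1.1), length.out = n_starts * n_par),
           n_starts, n_par)
}

.try_nlsLM <- function(formula, data, start, lower, upper) {
  tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper,
                      control = .fit_control()),
    error = function(e) NULL)
}

.multi_start_fit <- function(formula, data, start, lower, upper) {
  fits <- list()
  f0 <- .try_nlsLM(formula, data, start, lower, upper)
  if (!is.null(f0)) fits[[length(fits) + 1L]] <- f0
  # always explore the jittered starts and keep the lowest-RSS convergent
  # fit: nonlinear growth curves have flat valleys and the single start
  # occasionally settles in a poor one
  jf <- .jitter_factors(length(start))
  for (i in seq_len(nrow(jf))) {
    s <- mapply(function(v, f, lo, hi) min(max(v * f, lo), hi),
                unlist(start), jf[i, ], lower, upper)
    names(s) <- names(start)
    fi <- .try_nlsLM(formula, data, as.list(s), lower, upper)
    if (!is.null(fi)) fits[[length(fits) + 1L]] <- fi
  }
  if (!length(fits)) return(NULL)
  rss <- vapply(fits, function(f) sum(resid(f)^2), numeric(1))
  conv <- vapply(fits, function(f) isTRUE(f$convInfo$isConv), logical(1))
  if (any(conv)) fits[which(conv)][[which.min(rss[conv])]]
  else fits[[which.min(rss)]]
}

# per-x means: replicate readings share an x value, and finite-difference
# growth rates (used for data-driven starts) need one point per x
.date_means <- function(d) {
  agg <- tapply(d$y, d$x, mean)
  data.frame(x = as.numeric(names(agg)), y = as.numeric(agg))
}

.new_growth_fit <- function(model, fit, data, xvar, yvar, call,
                            param_builder) {
  if (is.null(fit)) {
    est <- setNames(rep(NA_real_, 3L), c("p1", "p2", "p3"))
    res <- list(model = model, fit = NULL, coefficients = est,
                rss = NA_real_, r_squared = NA_real_,
                converged = FALSE, iterations = 0L,
                data = data, xvar = xvar, yvar = yvar, call = call,
                parameters = NULL)
  } else {
    est <- coef(fit)
    y <- data$y
    rss <- sum(resid(fit)^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
    params <- tryCatch(param_builder(est), error = function(e) NULL)
    res <- list(model = model, fit = fit, coefficients = est,
                rss = rss, r_squared = r2,
                converged = isTRUE(fit$convInfo$isConv) && !is.null(params),
                iterations = fit$convInfo$finIter %||% NA_integer_,
                data = data, xvar = xvar, yvar = yvar, call = call,
                parameters = params)
  }
  class(res) <- c(paste0(model, "_fit"), "growth_fit")
  res
}

.as_xy_series <- function(series, xcands, ycands, what) {
  if (is.list(series) && !is.data.frame(series)) series <- as.data.frame(series)
  if (!is.data.frame(series)) stop_pg("'%s' must be a data frame", what)
  xn <- intersect(xcands, names(series))
  yn <- intersect(ycands, names(series))
  if (!length(xn) || !length(yn))
    stop_pg("'%s' needs columns (%s) and (%s)", what,
            paste(xcands, collapse = "|"), paste(ycands, collapse = "|"))
  out <- data.frame(x = as.numeric(series[[xn[1L]]]),
                    y = as.numeric(series[[yn[1L]]]))
  if (any(!is.finite(out$x)) || any(!is.finite(out$y)))
    stop_pg("'%s' contains non-finite values", what)
  out <- out[order(out$x), , drop = FALSE]   # fits are order-invariant
  rownames(out) <- NULL
  out
}

#' Fit the beta canopy-cover curve to observations
#'
#' Nonlinear least squares of the beta growth function against observed
#' canopy-cover fractions over thermal time (the conventional x-axis) or
#' calendar days. Rows are sorted internally, so the fit is invariant to
#' input order. When `init` is absent the start is data-driven: `wmax` =
#' maximum observed cover, `te` = last observed x, `tm` = x at the largest
#' finite-difference growth rate.
#'
#' @param series a data frame with columns `tt` (or `day`) and `cover`
#'   (fractions in \[0, 1\]); at least 4 observations.
#' @param init optional [canopy_parameters()] starting point.
#' @return a `"growth_fit"` object; inspect with `print`, `summary`,
#'   `coef`, and extract validated parameters from `$parameters`.
#'   `$converged` is `FALSE` (never an error) when the optimizer failed.
#' @export
#' @examples
#' p <- canopy_parameters(0.92, 449, 1027)
#' tt <- seq(40, 1300, length.out = 15)
#' fit <- fit_beta_canopy(data.frame(tt = tt, cover = beta_canopy(tt, p)))
#' coef(fit)
fit_beta_canopy <- function(series, init = NULL) {
  d <- .as_xy_series(series, c("tt", "day", "x"), c("cover", "y"), "series")
  if (any(d$y < 0 | d$y > 1)) stop_pg("cover values must lie in [0, 1]")
  if (nrow(d) < 4L)
    stop_pg("need at least 4 observations to fit 3 canopy parameters (got %d)",
            nrow(d))
  if (is.null(init)) {
    m <- .date_means(d)
    rate <- diff(m$y) / diff(m$x)
    start <- list(wmax = max(d$y), tm = m$x[which.max(rate)],
                  te = max(d$x))
  } else {
    start <- list(wmax = init$wmax, tm = init$tm, te = init$te)
  }
  xmax <- max(d$x)
  start$te <- min(max(start$te, start$tm + 1), 3 * xmax)
  fit <- .multi_start_fit(y ~ beta_canopy_raw(x, wmax, tm, te), d, start,
                          lower = c(wmax = 1e-3, tm = 0, te = 1),
                          upper = c(wmax = 1, tm = 0.99 * 3 * xmax, te = 3 * xmax))
  .new_growth_fit("beta", fit, d, "tt", "cover", match.call(),
                  function(est) canopy_parameters(est[["wmax"]], est[["tm"]],
                                                  est[["te"]]))
}

#' Fit the Gompertz harvest-index curve to observations
#'
#' Nonlinear least squares of `A * exp(-exp(-(t - Tu)/b))` against
#' observed harvest-index fractions over thermal time, with `A`
#' constrained to (0, 1\].
#'
#' @param series a data frame with columns `tt` (or `day`) and `hi`
#'   (fractions in \[0, 1\]); at least 4 observations.
#' @param init optional [partition_parameters()] starting point.
#' @return a `"growth_fit"` object (see [fit_beta_canopy()]).
#' @export
fit_gompertz_hi <- function(series, init = NULL) {
  d <- .as_xy_series(series, c("tt", "day", "x"), c("hi", "harvest_index", "y"),
                     "series")
  if (any(d$y < 0 | d$y > 1)) stop_pg("harvest-index values must lie in [0, 1]")
  if (nrow(d) < 4L)
    stop_pg("need at least 4 observations to fit 3 partition parameters (got %d)",
            nrow(d))
  if (is.null(init)) {
    m <- .date_means(d)
    rate <- diff(m$y) / diff(m$x)
    start <- list(a_max = max(max(d$y), 1e-3),
                  tu = m$x[min(which.max(rate) + 1L, nrow(m))],
                  b = diff(range(d$x)) / 5)
  } else {
    start <- list(a_max = init$a_max, tu = init$tu, b = init$b)
  }
  xmax <- max(d$x)
  start$tu <- min(max(start$tu, 1), 3 * xmax)
  start$b <- max(start$b, 1)
  fit <- .multi_start_fit(y ~ gompertz_raw(x, a_max, tu, b), d, start,
                          lower = c(a_max = 1e-3, tu = 1, b = 1),
                          upper = c(a_max = 1, tu = 3 * xmax, b = 3 * xmax))
  out <- .new_growth_fit("gompertz", fit, d, "tt", "hi", match.call(),
                         function(est) partition_parameters(est[["a_max"]],
                                                            est[["tu"]],
                                                            est[["b"]]))
  # a flat response (e.g. all-zero harvest indices) cannot identify the
  # curve: flag rather than return an arbitrary parameter vector
  if (out$converged && (sd(d$y) < 1e-12 || max(d$y) <= 0))
    out$converged <- FALSE
  out
}

#' Fit a logistic tuberization / yield curve
#'
#' Least squares of `K / (1 + exp(-r (t - t50)))` against cumulative tuber
#' yield over time; the maximum tuberization rate occurs at `t50`. Fits
#' with non-positive `r` (a non-increasing curve, outside the model's
#' shape) are flagged as non-convergent.
#'
#' @param curve a data frame with columns `day` (or `t`) and `yield` (or
#'   `y`); at least 4 points.
#' @param init optional named list with `k`, `r`, `t50` starting values.
#' @return a `"growth_fit"` object whose coefficients are `k` (asymptote),
#'   `r` (rate, d^-1) and `t50` (day of maximum rate).
#' @export
fit_logistic_curve <- function(curve, init = NULL) {
  d <- .as_xy_series(curve, c("day", "t", "x"), c("yield", "y"), "curve")
  if (nrow(d) < 4L)
    stop_pg("need at least 4 points to fit a logistic curve (got %d)", nrow(d))
  if (any(d$y < 0)) stop_pg("yields must be non-negative")
  if (is.null(init)) {
    k0 <- max(d$y) * 1.05 + 1e-9
    t50 <- d$x[which.min(abs(d$y - k0 / 2))]
    span <- max(diff(range(d$x)), 1)
    start <- list(k = k0, r = 4 / span, t50 = t50)
  } else {
    start <- list(k = init$k, r = init$r, t50 = init$t50)
  }
  span3 <- 3 * max(abs(d$x), 1)
  fit <- .multi_start_fit(y ~ logistic_raw(x, k, r, t50), d, start,
                          lower = c(k = 1e-9, r = -5, t50 = min(d$x) - span3),
                          upper = c(k = 10 * max(d$y) + 1, r = 5,
                                    t50 = max(d$x) + span3))
  out <- .new_growth_fit("logistic", fit, d, "day", "yield", match.call(),
                         function(est) {
                           if (est[["r"]] <= 0) stop("non-increasing curve")
                           list(k = est[["k"]], r = est[["r"]],
                                t50 = est[["t50"]])
                         })
  out$max_rate_day <- if (out$converged) out$coefficients[["t50"]] else NA_real_
  out
}

#' Radiation-use efficiency from the biomass-IPAR relation
#'
#' RUE (g MJ^-1) is the slope of the least-squares regression of total dry
#' biomass on cumulative intercepted PAR, through the origin (zero
#' interception implies zero growth); set `intercept = TRUE` for a
#' diagnostic fit with a free intercept.
#'
#' @param biomass a data frame with columns `day` and `total_dm`
#'   (g m^-2); the biomass-series container used across the package (a
#'   `tuber_dm` column, if present, is ignored here).
#' @param ipar_cumulative per-day cumulative intercepted PAR (MJ m^-2):
#'   a numeric vector indexed by day, covering every biomass sampling day.
#' @param intercept fit an intercept instead of forcing the origin.
#' @return a list of class `"rue_estimate"`: `rue`, `se`, `r_squared`,
#'   `n`, `intercept` (0 when forced), and the underlying `lm` fit.
#' @export
#' @examples
#' ipar <- cumsum(rep(8, 60))
#' days <- c(10, 20, 30, 40, 50, 60)
#' est <- estimate_rue(data.frame(day = days, total_dm = 3.13 * ipar[days]), ipar)
#' est$rue   # 3.13
estimate_rue <- function(biomass, ipar_cumulative, intercept = FALSE) {
  d <- .as_xy_series(biomass, c("day", "x"), c("total_dm", "biomass", "y"),
                     "biomass")
  if (nrow(d) < 2L) stop_pg("need at least 2 biomass samplings (got %d)", nrow(d))
  if (any(d$y < 0)) stop_pg("biomass must be non-negative")
  days <- as.integer(d$x)
  if (any(days < 1L) || any(days > length(ipar_cumulative)))
    stop_pg("biomass sampling day %d is outside the IPAR series (1..%d)",
            days[which(days < 1L | days > length(ipar_cumulative))][1L],
            length(ipar_cumulative))
  ipar <- ipar_cumulative[days]
  if (var(ipar) < .Machine$double.eps)
    stop_pg("cumulative IPAR has zero variance across sampling days")
  fit <- if (intercept) lm(d$y ~ ipar) else lm(d$y ~ 0 + ipar)
  sfit <- suppressWarnings(summary(fit))   # quiet on exact fits
  sm <- sfit$coefficients
  slope_row <- if (intercept) 2L else 1L
  structure(list(rue = unname(coef(fit)[["ipar"]]),
                 se = unname(sm[slope_row, "Std. Error"]),
                 r_squared = sfit$r.squared,
                 intercept = if (intercept) unname(coef(fit)[1L]) else 0,
                 n = nrow(d), fit = fit),
            class = "rue_estimate")
}

#' @export
print.rue_estimate <- function(x, ...) {
  cat(sprintf("RUE estimate: %.4g g/MJ (se %.3g, R^2 %.4f, n = %d)\n",
              x$rue, x$se, x$r_squared, x$n))
  invisible(x)
}

#' Days to reach 1% canopy cover by quadratic interpolation
#'
#' Fits a least-squares quadratic `cover(day)` to the early-season
#' observations (those up to the first local maximum of cover) and returns
#' the smallest real root of `cover(day) = target` inside the observed day
#' span — the standard early-vigour summary from repeated canopy imaging.
#'
#' @param series a data frame with columns `day` and `cover`; at least 3
#'   points spanning cover values below and above `target`.
#' @param target cover fraction to interpolate to (default 0.01).
#' @return the day (possibly fractional) at which cover reaches `target`.
#' @export
#' @examples
#' days <- 5:30
#' days_to_one_percent_cover(data.frame(day = days, cover = 1e-4 * days^2))  # 10
days_to_one_percent_cover <- function(series, target = 0.01) {
  d <- .as_xy_series(series, c("day", "x"), c("cover", "y"), "series")
  check_number(target, "target", lower = 0, upper = 1)
  # early-season window: observations up to the first local maximum
  imax <- which.max(d$y)
  d <- d[seq_len(imax), , drop = FALSE]
  if (nrow(d) < 3L)
    stop_pg("need at least 3 early-season points for a quadratic fit (got %d)",
            nrow(d))
  if (min(d$y) > target)
    stop_pg("all early-season covers exceed the %g target: no crossing in span",
            target)
  if (max(d$y) < target)
    stop_pg("no early-season cover reaches the %g target: no crossing in span",
            target)
  fit <- lm(y ~ x + I(x^2), data = d)
  cf <- coef(fit)   # (c0, c1, c2)
  roots <- polyroot(c(cf[[1L]] - target, cf[[2L]], cf[[3L]]))
  real <- Re(roots)[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))]
  span <- range(d$x)
  inside <- real[real >= span[1L] - 1e-9 & real <= span[2L] + 1e-9]
  if (!length(inside))
    stop_pg("the fitted quadratic has no real root in the observed day span")
  min(inside)
}

## ---- growth_fit methods -------------------------------------------------

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s growth-curve fit (%s vs %s)\n",
              switch(x$model, beta = "Beta canopy", gompertz = "Gompertz harvest-index",
                     logistic = "Logistic", x$model),
              x$yvar, x$xvar))
  if (!x$converged) cat("  ** did not converge **\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  RSS %.4g, R^2 %s, %s iterations, n = %d\n", x$rss,
              formatC(x$r_squared, digits = digits, format = "g"),
              x$iterations, nrow(x$data)))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$fit)) {
    cat("\nUnderlying nonlinear least-squares fit:\n")
    print(summary(object$fit))
  }
  invisible(object)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' Predict from a fitted growth curve
#'
#' @param object a `"growth_fit"` object.
#' @param newdata optional numeric vector (or data frame holding the fit's
#'   x variable) of thermal times / days; defaults to the fitted x values.
#' @param ... unused.
#' @return predicted response values.
#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$x
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    xn <- intersect(c(object$xvar, "x", "tt", "day"), names(newdata))
    if (!length(xn)) stop_pg("'newdata' has no '%s' column", object$xvar)
    as.numeric(newdata[[xn[1L]]])
  }
  est <- object$coefficients
  switch(object$model,
         beta = beta_canopy_raw(x, est[["wmax"]], est[["tm"]], est[["te"]]),
         gompertz = gompertz_raw(x, est[["a_max"]], est[["tu"]], est[["b"]]),
         logistic = logistic_raw(x, est[["k"]], est[["r"]], est[["t50"]]),
         stop_pg("unknown model '%s'", object$model))
}

#' @export
fitted.growth_fit <- function(object, ...) predict(object)

#' @export
residuals.growth_fit <- function(object, ...) object$data$y - fitted(object)

#' @export
plot.growth_fit <- function(x, n_grid = 200, ...) {
  grid <- seq(min(x$data$x), max(x$data$x), length.out = n_grid)
  plot(x$data$x, x$data$y, xlab = x$xvar, ylab = x$yvar,
       main = sprintf("%s fit", x$model), ...)
  lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Simulate new observations from a fitted growth curve
#'
#' Draws Gaussian noise around the fitted curve with the residual standard
#' deviation, at the fitted x positions — a parametric-bootstrap building
#' block.
#'
#' @param object a converged `"growth_fit"`.
#' @param nsim number of replicate series.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return a list of `nsim` data frames with the fit's x and y columns.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop_pg("cannot simulate from a non-convergent fit")
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sigma <- sqrt(object$rss / max(1L, nrow(object$data) - length(object$coefficients)))
  lapply(seq_len(nsim), function(i) {
    out <- data.frame(x = object$data$x, y = mu + rnorm(length(mu), 0, sigma))
    names(out) <- c(object$xvar, object$yvar)
    out
  })
}
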