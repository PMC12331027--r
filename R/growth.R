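#' Canopy-cover (beta growth function) parameters
#'
#' The beta growth function describes the rise of fractional ground cover
#' with thermal time `t`:
#' \deqn{W(t) = W_{max} \left(1 + \frac{t_e - t}{t_e - t_m}\right)
#'       \left(\frac{t}{t_e}\right)^{t_e / (t_e - t_m)}, \quad 0 \le t_m < t_e}
#' `wmax` is the maximum cover, `tm` the thermal time at the maximum
#' canopy growth rate (the inflection) and `te` the thermal time at which
#' maximum cover is reached.
#'
#' @param wmax maximum canopy cover, a fraction in (0, 1].
#' @param tm thermal time at maximum canopy growth rate (degree C d),
#'   `0 <= tm < te`.
#' @param te thermal time at maximum canopy cover (degree C d).
#' @return an object of class `"canopy_parameters"`.
#' @seealso [beta_canopy()], [fit_beta_canopy()]
#' @export
canopy_parameters <- function(wmax, tm, te) {
  check_number(wmax, "wmax")
  check_number(tm, "tm")
  check_number(te, "te")
  if (wmax <= 0 || wmax > 1) stop_pg("wmax = %g must be in (0, 1]", wmax)
  if (tm < 0 || tm >= te) stop_pg("need 0 <= tm < te (got tm = %g, te = %g)", tm, te)
  structure(list(wmax = wmax, tm = tm, te = te), class = "canopy_parameters")
}

#' Tuber-partition (Gompertz harvest-index) parameters
#'
#' The harvest index (tuber dry mass over whole-plant dry mass) rises with
#' thermal time `t` along a Gompertz curve
#' \deqn{HI(t) = A \, e^{-e^{-(t - T_u)/b}}}
#' where `a_max` (A) is the maximum harvest index, `tu` the thermal time
#' at the maximum partition rate (the inflection, where `HI = A/e`) and
#' `b` the thermal-time scale of the rise.
#'
#' @param a_max maximum harvest index, a fraction in (0, 1].
#' @param tu thermal time at maximum tuber-partition rate (degree C d), > 0.
#' @param b thermal-time scale (degree C d), > 0.
#' @return an object of class `"partition_parameters"`.
#' @seealso [gompertz_partition()], [fit_gompertz_hi()], [tuber_initiation_tt()]
#' @export
partition_parameters <- function(a_max, tu, b) {
  check_number(a_max, "a_max")
  check_number(tu, "tu")
  check_number(b, "b")
  if (a_max <= 0 || a_max > 1) stop_pg("a_max = %g must be in (0, 1]", a_max)
  if (tu <= 0) stop_pg("tu = %g must be > 0", tu)
  if (b <= 0) stop_pg("b = %g must be > 0", b)
  structure(list(a_max = a_max, tu = tu, b = b), class = "partition_parameters")
}

# raw kernels used both by the public evaluators and by the nls fitters
beta_canopy_raw <- function(tt, wmax, tm, te) {
  w <- ifelse(tt >= te, wmax,
              wmax * (1 + (te - tt) / (te - tm)) * (tt / te)^(te / (te - tm)))
  pmin(pmax(w, 0), wmax)
}

gompertz_raw <- function(tt, a_max, tu, b) a_max * exp(-exp(-(tt - tu) / b))

logistic_raw <- function(t, k, r, t50) k / (1 + exp(-r * (t - t50)))

#' Evaluate the beta canopy-cover function
#'
#' Returns the canopy-cover fraction at thermal time `tt`. Beyond `te`
#' cover is held at `wmax` (senescence, when wanted, is applied by the
#' simulator, not here); values are clamped to `[0, wmax]` to guard
#' floating-point overshoot at the endpoints.
#'
#' @param tt thermal time (degree C d), non-negative; vectorized.
#' @param p a [canopy_parameters()] object.
#' @return canopy cover fraction(s) in `[0, wmax]`.
#' @export
#' @examples
#' p <- canopy_parameters(wmax = 1, tm = 243, te = 1145)
#' beta_canopy(c(0, 600, 1145, 2000), p)
beta_canopy <- function(tt, p) {
  if (!inherits(p, "canopy_parameters"))
    p <- do.call(canopy_parameters, as.list(p)[c("wmax", "tm", "te")])
  if (any(!is.finite(tt)) || any(tt < 0))
    stop_pg("'tt' must be finite and >= 0")
  beta_canopy_raw(tt, p$wmax, p$tm, p$te)
}

#' Evaluate the Gompertz tuber-partition (harvest index) function
#'
#' @param tt thermal time (degree C d), non-negative; vectorized.
#' @param p a [partition_parameters()] object.
#' @return harvest-index fraction(s) in `(0, a_max)`, strictly increasing
#'   in `tt` with asymptote `a_max`; at `tt = tu` the value is exactly
#'   `a_max / e`.
#' @export
#' @examples
#' p <- partition_parameters(a_max = 1, tu = 1044, b = 473)
#' gompertz_partition(1044, p)   # 1/e
gompertz_partition <- function(tt, p) {
  if (!inherits(p, "partition_parameters"))
    p <- do.call(partition_parameters, as.list(p)[c("a_max", "tu", "b")])
  if (any(!is.finite(tt)) || any(tt < 0))
    stop_pg("'tt' must be finite and >= 0")
  gompertz_raw(tt, p$a_max, p$tu, p$b)
}

#' Thermal time of tuber initiation
#'
#' Tuber initiation is taken as the thermal time at which the partition
#' function first reaches a minimal threshold; since the Gompertz curve is
#' strictly increasing the crossing is unique and available analytically:
#' `tt = tu - b * log(-log(threshold / a_max))`.
#'
#' @param p a [partition_parameters()] object.
#' @param threshold harvest-index threshold, strictly between 0 and
#'   `a_max`; default 0.01 (a 1% partition fraction).
#' @return thermal time (degree C d) at which the partition function
#'   equals `threshold`.
#' @export
#' @examples
#' p <- partition_parameters(1, tu = 500, b = 100)
#' tuber_initiation_tt(p, threshold = 1 / exp(1))  # 500, the inflection
tuber_initiation_tt <- function(p, threshold = 0.01) {
  if (!inherits(p, "partition_parameters"))
    p <- do.call(partition_parameters, as.list(p)[c("a_max", "tu", "b")])
  check_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= p$a_max)
    stop_pg("threshold = %g must lie strictly between 0 and a_max = %g",
            threshold, p$a_max)
  p$tu - p$b * log(-log(threshold / p$a_max))
}
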