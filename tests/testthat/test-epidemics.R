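test_that("AUDPC midpoint formula matches hand values and the trapezoid oracle", {
  expect_equal(audpc(c(0, 10, 20), c(0, 10, 30)), 250)
  # constant severity over a span is a rectangle
  expect_equal(audpc(c(5, 12, 40), rep(35, 3)), 35 * 35)
  expect_error(audpc(c(0, 10), 50), "length")
  expect_error(audpc(data.frame(day = 5, severity = 10)), "at least 2")
  expect_error(audpc(c(0, 10, 5), c(1, 2, 3)), "strictly increasing")

  set.seed(17)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    t <- sort(runif(n, 0, 120))
    y <- runif(n, 0, 100)
    expect_equal(audpc(t, y), pracma::trapz(t, y), tolerance = 1e-12)
  }
})

test_that("AUDPC is additive over time partitions and collinear insertions", {
  t <- c(0, 8, 20, 33, 47)
  y <- c(0, 5, 22, 60, 85)
  a_full <- audpc(t, y)
  expect_equal(audpc(t[1:3], y[1:3]) + audpc(t[3:5], y[3:5]), a_full)
  # inserting a reading on the connecting segment changes nothing
  t_mid <- 26.5
  y_mid <- 22 + (60 - 22) * (t_mid - 20) / (33 - 20)
  expect_equal(audpc(sort(c(t, t_mid)), append(y, y_mid, after = 3)), a_full)
})

test_that("disease index normalizes AUDPC to the worst-case epidemic", {
  a <- disease_assessment("g", "uncontrolled", c(0, 50), c(100, 100))
  expect_equal(disease_index(a), 1)
  expect_equal(disease_index(disease_assessment("g", "controlled",
                                                c(0, 50), c(0, 0))), 0)
})

test_that("disease-yield regression recovers exact and noisy lines", {
  idx <- c(0.05, 0.2, 0.45, 0.7, 0.9)
  exact <- disease_yield_regression(
    data.frame(index = idx, yield = -2351 * idx + 3553))
  expect_equal(exact$slope, -2351, tolerance = 1e-10)
  expect_equal(exact$intercept, 3553, tolerance = 1e-10)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  flat <- disease_yield_regression(data.frame(index = idx, yield = rep(7, 5)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  set.seed(23)
  noisy <- data.frame(index = idx, yield = -2351 * idx + 3553 + rnorm(5, 0, 40))
  expect_equal(disease_yield_regression(noisy)$slope, -2351, tolerance = 0.1)

  expect_warning(disease_yield_regression(
    data.frame(index = idx, yield = 10 * idx)), "positive")
  expect_error(disease_yield_regression(
    data.frame(index = rep(1, 5), yield = 1:5)), "zero variance")
})

test_that("logistic curve fitting recovers truth and flags decreasing series", {
  t <- seq(10, 110, length.out = 12)
  y <- 50 / (1 + exp(-0.1 * (t - 60)))
  fit <- fit_logistic_curve(data.frame(day = t, yield = y))
  expect_true(fit$converged)
  expect_equal(coef(fit)[["k"]], 50, tolerance = 1e-3)
  expect_equal(coef(fit)[["r"]], 0.1, tolerance = 1e-3)
  expect_equal(coef(fit)[["t50"]], 60, tolerance = 1e-3)
  expect_equal(fit$max_rate_day, coef(fit)[["t50"]])

  set.seed(41)
  noisy <- data.frame(day = t, yield = pmax(0, y + rnorm(12, 0, 1)))
  est <- coef(fit_logistic_curve(noisy))
  expect_equal(est[["k"]], 50, tolerance = 0.05)
  expect_equal(est[["t50"]], 60, tolerance = 0.05)

  decreasing <- data.frame(day = t, yield = rev(y))
  expect_false(fit_logistic_curve(decreasing)$converged)
})

test_that("yield increase and max-rate shift compare the two treatments", {
  t <- seq(10, 130, by = 10)
  curve_from <- function(k, t50, treatment)
    yield_curve("g", treatment, t, k / (1 + exp(-0.12 * (t - t50))))
  ctrl <- curve_from(43, 87, "controlled")
  unctrl <- curve_from(20, 60, "uncontrolled")

  expect_equal(yield_increase_percent(ctrl, unctrl), 115, tolerance = 0.01)
  expect_equal(yield_increase_percent(unctrl, unctrl), 0)
  expect_equal(yield_increase_percent(curve_from(28.55, 60, "controlled"),
                                      curve_from(20, 60, "uncontrolled")),
               42.75, tolerance = 0.01)

  # the 27-day delay of the fastest tuberization under control
  expect_equal(max_rate_shift_days(ctrl, unctrl), 27, tolerance = 0.01)
  expect_equal(max_rate_shift_days(unctrl, unctrl), 0, tolerance = 1e-6)
  expect_equal(max_rate_shift_days(unctrl, ctrl), -27, tolerance = 0.01)

  expect_error(yield_increase_percent(ctrl,
    yield_curve("g", "uncontrolled", t, rep(0, length(t)))), "zero")
})
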