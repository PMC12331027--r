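test_that("beta canopy fit recovers noise-free truth to 0.1%", {
  p <- canopy_parameters(0.92, 449, 1027)
  tt <- seq(40, 1300, length.out = 15)
  fit <- fit_beta_canopy(canopy_series_from(p, tt))
  expect_true(fit$converged)
  est <- coef(fit)
  expect_equal(est[["wmax"]], 0.92, tolerance = 1e-3)
  expect_equal(est[["tm"]], 449, tolerance = 1e-3)
  expect_equal(est[["te"]], 1027, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
  expect_s3_class(fit$parameters, "canopy_parameters")
})

test_that("beta canopy fit recovers noisy truth within 5%", {
  set.seed(2024)
  p <- canopy_parameters(0.92, 449, 1027)
  tt <- seq(30, 1400, length.out = 20)
  d <- canopy_series_from(p, tt)
  d$cover <- pmin(1, pmax(0, d$cover + rnorm(20, 0, 0.02)))
  est <- coef(fit_beta_canopy(d))
  expect_equal(est[["wmax"]], 0.92, tolerance = 0.05)
  expect_equal(est[["tm"]], 449, tolerance = 0.05)
  expect_equal(est[["te"]], 1027, tolerance = 0.05)
})

test_that("fits are invariant to row order and refuse under-determined input", {
  p <- canopy_parameters(0.9, 300, 1000)
  tt <- seq(50, 1200, length.out = 12)
  d <- canopy_series_from(p, tt)
  set.seed(5)
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(coef(fit_beta_canopy(shuffled)), coef(fit_beta_canopy(d)))
  expect_error(fit_beta_canopy(d[1:3, ]), "at least 4")
  expect_error(fit_gompertz_hi(data.frame(tt = 1:3, hi = c(0, .1, .2))),
               "at least 4")
})

test_that("gompertz harvest-index fit recovers truth and flags flat series", {
  p <- partition_parameters(0.97, 545, 186)
  tt <- seq(50, 1600, length.out = 15)
  fit <- fit_gompertz_hi(hi_series_from(p, tt))
  expect_true(fit$converged)
  expect_equal(coef(fit)[["a_max"]], 0.97, tolerance = 1e-3)
  expect_equal(coef(fit)[["tu"]], 545, tolerance = 1e-3)
  expect_equal(coef(fit)[["b"]], 186, tolerance = 1e-3)

  set.seed(99)
  d <- hi_series_from(p, tt)
  d$hi <- pmin(1, pmax(0, d$hi + rnorm(15, 0, 0.03)))
  est <- coef(fit_gompertz_hi(d))
  expect_equal(est[["a_max"]], 0.97, tolerance = 0.05)
  expect_equal(est[["tu"]], 545, tolerance = 0.05)
  expect_equal(est[["b"]], 186, tolerance = 0.05)

  flat <- data.frame(tt = tt, hi = rep(0, 15))
  expect_false(fit_gompertz_hi(flat)$converged)
})

test_that("every bundled parameter row round-trips through a dense refit", {
  tab <- all_parameter_rows()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    tt <- seq(20, 1.4 * row$te, length.out = 25)
    cfit <- coef(fit_beta_canopy(canopy_series_from(
      canopy_parameters(row$wmax, row$tm, row$te), tt)))
    expect_equal(unname(cfit), c(row$wmax, row$tm, row$te), tolerance = 1e-4)
    tt2 <- seq(20, max(2.2 * row$tu, 1500), length.out = 25)
    gfit <- coef(fit_gompertz_hi(hi_series_from(
      partition_parameters(row$a_max, row$tu, row$b), tt2)))
    expect_equal(unname(gfit), c(row$a_max, row$tu, row$b), tolerance = 1e-4)
  }
})

test_that("RUE is the through-origin slope of biomass on cumulative IPAR", {
  ipar <- cumsum(rep(8.2, 120))
  days <- c(15, 35, 55, 75, 95, 115)
  est <- estimate_rue(data.frame(day = days, total_dm = 3.13 * ipar[days]), ipar)
  expect_equal(est$rue, 3.13, tolerance = 1e-12)
  expect_equal(est$intercept, 0)

  set.seed(1)
  noisy <- data.frame(day = days,
                      total_dm = 3.13 * ipar[days] * (1 + rnorm(6, 0, 0.05)))
  expect_equal(estimate_rue(noisy, ipar)$rue, 3.13, tolerance = 0.03)

  expect_error(estimate_rue(data.frame(day = 10, total_dm = 100), ipar),
               "at least 2")
  expect_error(estimate_rue(data.frame(day = days, total_dm = 1:6),
                            rep(5, 120)), "zero variance")
  expect_error(estimate_rue(data.frame(day = c(10, 500), total_dm = c(1, 2)),
                            ipar), "outside the IPAR series")
})

test_that("days to 1% cover interpolates the early-season quadratic", {
  days <- 5:30
  d <- data.frame(day = days, cover = 1e-4 * days^2)
  expect_equal(days_to_one_percent_cover(d), 10, tolerance = 1e-8)

  set.seed(31)
  noisy <- data.frame(day = days,
                      cover = pmax(0, 1e-4 * days^2 + rnorm(26, 0, 5e-4)))
  expect_equal(days_to_one_percent_cover(noisy), 10, tolerance = 1)

  high <- data.frame(day = days, cover = 0.2 + 1e-4 * days^2)
  expect_error(days_to_one_percent_cover(high), "no crossing")
})

test_that("growth_fit objects behave like fitted models", {
  p <- canopy_parameters(0.9, 300, 1000)
  tt <- seq(50, 1200, length.out = 12)
  fit <- fit_beta_canopy(canopy_series_from(p, tt))
  expect_equal(length(residuals(fit)), 12)
  expect_equal(fitted(fit) + residuals(fit), fit$data$y)
  expect_equal(predict(fit, 1000), 0.9, tolerance = 1e-3)
  expect_output(print(fit), "Beta canopy")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_named(sims[[1]], c("tt", "cover"))
})
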