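grid_curve <- function(f, step = 0.1) {
  hour <- seq(0, 24 - step, by = step)
  data.frame(hour = hour, f = f(hour))
}

test_that("parabolic peak width follows the half-hour difference formula", {
  # f(t) = H - a (t - t*)^2 near the peak: mean drop half an hour either
  # side is exactly 0.25 a
  for (a in c(2, 10, 36)) {
    cv <- grid_curve(function(t) 100 - a * pmin((t - 12)^2, 50))
    ft <- extract_features(cv, prob_range = c(0.1, 0.9))
    expect_equal(ft$peak_width, 0.25 * a, tolerance = 1e-10)
    expect_equal(ft$peak_time_h, 12)
  }
})

test_that("a uniform curve puts 8/24 of intake at night", {
  cv <- grid_curve(function(t) rep(55, length(t)))
  ft <- extract_features(cv, prob_range = c(0.5, 0.5))
  expect_equal(ft$night_prop, 8 / 24, tolerance = 1e-10)
  expect_equal(ft$n_peaks, 0) # constant curve has no peaks
  # bin-sum mode agrees for a flat curve
  ftb <- extract_features(cv, prob_range = c(0.5, 0.5), night_mode = "bins")
  expect_equal(ftb$night_prop, 8 / 24, tolerance = 1e-10)
})

test_that("cosine curve features match the closed form on the 0.1 h grid", {
  cv <- grid_curve(function(t) 100 + 50 * cos(2 * pi * (t - 16) / 24))
  ft <- extract_features(cv, prob_range = c(0.2, 0.8))
  expect_equal(ft$n_peaks, 1)
  expect_equal(ft$peak_time_h, 16)
  expect_equal(ft$peak_height, 150)
  expect_equal(ft$lowest_intake, 50, tolerance = 1e-6)
  expect_equal(ft$min_prob_eat, 0.2)
  expect_equal(ft$max_prob_eat, 0.8)
})

test_that("features are scale-equivariant and rotation-equivariant", {
  f0 <- function(t) 80 + 40 * cos(2 * pi * (t - 16) / 24) +
    15 * cos(4 * pi * (t - 4) / 24)
  base <- extract_features(grid_curve(f0), prob_range = c(0, 1))
  for (c_mult in c(0.5, 3)) {
    sc <- extract_features(grid_curve(function(t) c_mult * f0(t)),
                           prob_range = c(0, 1))
    expect_equal(sc$peak_height, c_mult * base$peak_height)
    expect_equal(sc$peak_width, c_mult * base$peak_width)
    expect_equal(sc$lowest_intake, c_mult * base$lowest_intake)
    expect_equal(sc$peak_time_h, base$peak_time_h)
    expect_equal(sc$n_peaks, base$n_peaks)
    expect_equal(sc$night_prop, base$night_prop, tolerance = 1e-10)
  }
  for (k in c(3, 11.5)) {
    rot <- extract_features(grid_curve(function(t) f0((t - k) %% 24)),
                            prob_range = c(0, 1))
    expect_equal(rot$peak_time_h, (base$peak_time_h + k) %% 24,
                 tolerance = 0.11)
    expect_equal(rot$n_peaks, base$n_peaks)
    expect_equal(rot$peak_height, base$peak_height, tolerance = 1e-6)
  }
})

test_that("peak counting matches programmed profile shapes", {
  two <- grid_curve(function(t) 1 + 0.5 * exp(-pmin(abs(t - 10), 24 - abs(t - 10))^2 / 2) +
                      exp(-pmin(abs(t - 16), 24 - abs(t - 16))^2 / 3))
  one <- grid_curve(function(t) 1 + exp(-pmin(abs(t - 16), 24 - abs(t - 16))^2 / 3))
  expect_equal(extract_features(two, prob_range = c(0, 1))$n_peaks, 2)
  expect_equal(extract_features(one, prob_range = c(0, 1))$n_peaks, 1)
  # peak spanning midnight is counted once, via the cyclic wrap
  wrap <- grid_curve(function(t) 1 + exp(-pmin(abs(t - 0.2), 24 - abs(t - 0.2))^2 / 3))
  expect_equal(extract_features(wrap, prob_range = c(0, 1))$n_peaks, 1)
})

test_that("plateau tops count once, at their first point", {
  f <- function(t) pmin(1 + pmax(0, 2 - abs(t - 12)), 2)
  ft <- extract_features(grid_curve(f), prob_range = c(0, 1))
  expect_equal(ft$n_peaks, 1)
})

test_that("de-trended curves are identical across trend levels", {
  # same diurnal shape, trend doubling between periods: de-trended
  # prediction removes the difference
  prof <- profile_alternans(consistency = 1)
  spec <- tiny_spec(n_days = 28, seed = 71,
                    trend = function(day) ifelse(day <= 14, 1, 2))
  set.seed(71)
  s <- generate_hourly(prof, spec)
  fit <- fit_hurdle(s)
  c1 <- detrend_prediction(fit, 1)
  c2 <- detrend_prediction(fit, 2)
  # shapes agree once each is scaled by its own mean level
  expect_lt(max(abs(c1$f / mean(c1$f) - c2$f / mean(c2$f))) /
              diff(range(c1$f / mean(c1$f))), 0.2)
})

test_that("non-finite curves are rejected", {
  cv <- grid_curve(function(t) rep(1, length(t)))
  cv$f[5] <- NaN
  expect_error(extract_features(cv, prob_range = c(0, 1)), "non-finite")
})

test_that("circadian join adds proportions only for matched pig-periods", {
  feats <- data.frame(pig_id = c("a", "a", "b"), pen_id = "p",
                      period_id = c(1, 2, 1), n_peaks = 2)
  rhythm <- data.frame(pig_id = c("a", "b"), group = c(1, 1),
                       proportion_circadian = c(0.8, 0.3))
  j <- join_circadian(feats, rhythm)
  expect_equal(j$prop_circadian_days, c(0.8, NA, 0.3))
  expect_equal(nrow(j), 3)
})
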