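test_that("transforms apply the stated arithmetic", {
  df <- data.frame(period_id = rep(1:5, each = 4),
                   peak_time_h = rep(16, 20), night_prop = runif(20))
  tc <- transform_and_check(df, list(
    peak_time_h = list(type = "const_minus_sqrt", const = 24),
    night_prop = list(type = "identity")))
  expect_equal(tc$features$peak_time_h, rep(24 - 4, 20))
  expect_identical(tc$features$night_prop, df$night_prop)
})

test_that("domain violations fail naming the offending rows", {
  df <- data.frame(period_id = 1:3, lowest_intake = c(4, -1, 9))
  expect_error(transform_and_check(df, list(lowest_intake = list(type = "sqrt"))),
               "rows: 2")
  df2 <- data.frame(period_id = 1:3, peak_width = c(4, 0, 9))
  expect_error(transform_and_check(df2, list(peak_width = list(type = "log"))),
               "rows: 2")
})

test_that("log transform normalises a lognormal feature", {
  ok <- logical(20)
  for (i in seq_len(20)) {
    set.seed(i)
    df <- data.frame(period_id = rep(1:5, each = 30),
                     peak_height = exp(rnorm(150, 5, 0.6)))
    tc <- transform_and_check(df, list(peak_height = list(type = "log")))
    ok[i] <- tc$normality$ok[1]
  }
  expect_gt(mean(ok), 0.95)
})

test_that("the period mixed model recovers known variance components", {
  d <- sim_feature_cohort(seed = 81)
  pm <- fit_period_model(d)
  expect_equal(pm$var_pig, 1, tolerance = 0.35)
  expect_equal(pm$var_resid, 0.75, tolerance = 0.35)
  icc <- compute_icc(pm)
  expect_equal(icc$icc[icc$component == "pig"], 0.5, tolerance = 0.15)
})

test_that("permuting pig labels within pens destroys the pig ICC only", {
  d <- sim_feature_cohort(seed = 82, var_pig = 2, var_pen = 1, var_resid = 0.5,
                          rho = 0)
  icc0 <- compute_icc(fit_period_model(d))
  # shuffle values across pigs within each pen-period cell
  set.seed(83)
  dp <- d
  for (pen in unique(d$pen_id)) for (p in unique(d$period_id)) {
    i <- which(dp$pen_id == pen & dp$period_id == p)
    dp$value[i] <- dp$value[sample(i)]
  }
  iccp <- compute_icc(fit_period_model(dp))
  expect_gt(icc0$icc[icc0$component == "pig"], 0.4)
  expect_lt(iccp$icc[iccp$component == "pig"], 0.15)
  # pen share survives the within-pen shuffle
  expect_equal(iccp$icc[iccp$component == "pen"],
               icc0$icc[icc0$component == "pen"], tolerance = 0.15)
})

test_that("icc formula and strength bands follow their definitions", {
  pm <- structure(list(var_pig = 1, var_pen = 0, var_resid = 1,
                       ar1_rho = 0, singular = FALSE),
                  class = "period_model")
  icc <- compute_icc(pm)
  expect_equal(icc$icc, c(0.5, 0, 0.5))
  expect_equal(icc$label, c("moderate", "weak", "moderate"))
  pm2 <- structure(list(var_pig = 0, var_pen = 3, var_resid = 1,
                        ar1_rho = 0, singular = FALSE),
                   class = "period_model")
  icc2 <- compute_icc(pm2)
  expect_equal(icc2$icc[icc2$component == "pen"], 0.75)
  expect_equal(icc2$label[icc2$component == "pen"], "strong")
  expect_equal(sum(icc$icc), 1)
  pm0 <- structure(list(var_pig = 0, var_pen = 0, var_resid = 0),
                   class = "period_model")
  expect_error(compute_icc(pm0), "undefined")
})

test_that("period effect test finds a programmed trend and reports letters", {
  d <- sim_feature_cohort(seed = 84, var_pig = 0.5, var_pen = 0.1,
                          var_resid = 0.4,
                          period_effects = seq(0, 1.4, length.out = 5))
  pm <- fit_period_model(d)
  te <- test_period_effect(pm)
  expect_lt(te$p, 0.05)
  expect_false(is.null(te$letters))
  # extreme periods get different letters
  expect_false(te$letters[["1"]] == te$letters[["5"]])
})

test_that("model preconditions are enforced", {
  d <- sim_feature_cohort(seed = 85)
  expect_error(fit_period_model(d[d$period_id == 1, ]), "2 periods")
  expect_error(fit_period_model(d[d$pen_id == "pen01", ]), "2 pens")
})

test_that("spearman matrices are symmetric, unit-diagonal, monotone-invariant", {
  set.seed(86)
  df <- data.frame(period_id = 1, pig_id = 1:30, pen_id = "a",
                   peak_height = rlnorm(30), night_prop = runif(30))
  df$peak_width <- exp(df$peak_height) # monotone map: rho exactly 1
  sm <- spearman_matrix(df, period = 1,
                        cols = c("peak_height", "peak_width", "night_prop"))
  expect_equal(sm$rho, t(sm$rho))
  expect_equal(diag(sm$rho), c(peak_height = 1, peak_width = 1, night_prop = 1))
  expect_equal(sm$rho["peak_height", "peak_width"], 1)
  expect_equal(sm$labels["peak_height", "peak_width"], "strong")
})

test_that("constant feature columns are flagged", {
  df <- data.frame(period_id = 1, pig_id = 1:10, pen_id = "a",
                   night_prop = runif(10), n_peaks = 2)
  sm <- spearman_matrix(df, period = 1, cols = c("night_prop", "n_peaks"))
  expect_equal(sm$constant_cols, "n_peaks")
  expect_true(is.na(sm$rho["night_prop", "n_peaks"]))
})

test_that("strength bands classify boundary values correctly", {
  expect_equal(strength_label(c(0.39, 0.4, 0.59, 0.6, -0.41, -0.6, NA)),
               c("weak", "moderate", "moderate", "strong", "moderate",
                 "strong", NA))
})
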