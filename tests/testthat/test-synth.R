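test_that("degenerate profiles generate deterministic series", {
  spec <- tiny_spec(n_days = 5)
  set.seed(1)
  s <- generate_hourly(constant_profile(p = 1, mu = 100), spec)
  # p_eat = 1 everywhere: every hour has positive intake near 100 g
  expect_true(all(s$values > 0))
  expect_equal(mean(s$values), 100, tolerance = 0.1)

  s0 <- generate_hourly(constant_profile(p = 0, mu = 100), spec)
  expect_true(all(s0$values == 0))
})

test_that("profile validation rejects malformed inputs", {
  expect_error(diurnal_profile("flat", rep(0.5, 23), rep(100, 24)), "length")
  expect_error(diurnal_profile("flat", rep(1.5, 24), rep(100, 24)), "\\[0, 1\\]")
  expect_error(diurnal_profile("flat", rep(0.5, 24), rep(-1, 24)), ">= 0")
  expect_error(cohort_spec(ar1_rho = 1), "rho")
})

test_that("empirical hourly means recover trend x p_eat x mu_intake", {
  # analytic expectation: E[intake at hour h, day d] = trend(d) p_eat[h] mu[h]
  prof <- profile_alternans(consistency = 1) # no jitter
  n_days <- 250
  spec <- tiny_spec(n_days = n_days, seed = 11,
                    trend = function(day) 1 + 0.5 * (day > 100))
  set.seed(11)
  s <- generate_hourly(prof, spec)
  tr <- ifelse(seq_len(n_days) > 100, 1.5, 1)
  got <- s$values
  # per-hour analytic mean and variance of Bernoulli(p) x Gamma(k, mean m):
  # E = p m, var = p m^2 (1 + 1/k) - (p m)^2; check a 4-sigma band
  k <- spec$gamma_shape
  for (reg in list(1:100, 101:250)) {
    m_h <- mean(tr[reg]) * prof$mu_intake
    m2_h <- mean(tr[reg]^2) * prof$mu_intake^2
    e_h <- prof$p_eat * m_h
    v_h <- prof$p_eat * m2_h * (1 + 1 / k) - e_h^2 +
      (m2_h - m_h^2 / 1) * 0 # trend is piecewise constant within regimes
    emp <- colMeans(got[reg, ])
    se <- sqrt(v_h / length(reg))
    expect_true(all(abs(emp - e_h) < pmax(4 * se, 1e-8)))
  }
})

test_that("visit explosion conserves mass and round-trips bit-exactly", {
  spec <- tiny_spec(n_days = 20, seed = 3, missing_day_prob = 0.1)
  set.seed(3)
  s <- generate_hourly(profile_alternans(), spec)
  v <- generate_visits(s)
  # per-hour conservation
  agg <- aggregate_hourly(v, n_days = 20)
  expect_length(agg, 1)
  vals <- s$values; vals[is.na(vals)] <- 0
  expect_identical(as.vector(vals), as.vector(agg[[1]]$values))
  # zero hours emit no visits
  long <- hourly_long(s)
  expect_equal(nrow(v[v$intake_g > 0, ]), nrow(v))
})

test_that("whole cohort round-trips through visits", {
  spec <- cohort_spec(n_pens = 2, pigs_per_pen = 2, n_days = 15, seed = 5,
                      missing_day_prob = 0.05)
  co <- simulate_cohort(spec, profiles = list(profile_alternans(),
                                              profile_night_feeder()))
  agg <- aggregate_hourly(co$visits, n_days = 15)
  for (s in co$hourly) {
    vals <- s$values; vals[is.na(vals)] <- 0
    expect_identical(as.vector(vals), as.vector(agg[[s$pig_id]]$values))
  }
})

test_that("error injection matches its rates and labels", {
  v <- toy_visits(n = 1000)
  # identity case
  set.seed(2)
  out0 <- inject_errors(v, error_spec(0, 0, 0))
  expect_identical(out0$visits, v)
  expect_true(all(out0$labels$label == "clean"))
  # saturating case
  set.seed(2)
  out1 <- inject_errors(v, error_spec(neg_intake_rate = 1))
  expect_true(all(out1$visits$intake_g < 0))
  expect_true(all(out1$labels$label == "corrupted"))
  # binomial bound: 3 independent rates of 0.05 each; P(corrupted) = 1-0.95^3
  set.seed(7)
  out <- inject_errors(v, error_spec(0.05, 0.05, 0.05))
  frac <- mean(out$labels$label == "corrupted")
  p <- 1 - 0.95^3
  half_width <- qnorm(0.995) * sqrt(p * (1 - p) / 1000)
  expect_gt(frac, p - half_width)
  expect_lt(frac, p + half_width)
})

test_that("identical spec and seed give identical cohorts", {
  spec <- cohort_spec(n_pens = 1, pigs_per_pen = 2, n_days = 10, seed = 99)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$visits, b$visits)
  expect_identical(lapply(a$hourly, `[[`, "values"),
                   lapply(b$hourly, `[[`, "values"))
})

test_that("generated series carry their ground truth", {
  spec <- tiny_spec(n_days = 5)
  set.seed(1)
  prof <- profile_single_peak()
  s <- generate_hourly(prof, spec)
  tr <- attr(s, "truth")
  expect_identical(tr$profile$p_eat, prof$p_eat)
  expect_identical(tr$profile$pattern_kind, "single_peak")
})
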