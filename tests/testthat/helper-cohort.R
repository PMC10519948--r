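# Shared fixtures: small deterministic cohorts and series built in code.

tiny_spec <- function(n_days = 28, seed = 42, missing_day_prob = 0,
                      trend = function(day) 1, ...) {
  cohort_spec(n_pens = 1, pigs_per_pen = 1, n_days = n_days, trend = trend,
              missing_day_prob = missing_day_prob, seed = seed, ...)
}

# deterministic profile: eats every hour with fixed intake
constant_profile <- function(p = 1, mu = 100, consistency = 1) {
  diurnal_profile("flat", rep(p, 24), rep(mu, 24), consistency)
}

# pure cosine hourly series wrapped as a detrended_series-like vector
cosine_series <- function(n_days = 28, period = 24, amp = 1, noise_sd = 0) {
  t <- seq_len(n_days * 24)
  amp * cos(2 * pi * t / period) + stats::rnorm(length(t), 0, noise_sd)
}

# pig-period feature values with known variance components and AR(1)
# period-to-period residuals (thin wrapper fixing the seed argument order)
sim_feature_cohort <- function(seed, ...) {
  simulate_feature_table(seed = seed, ...)
}

# toy visit table: `n` clean within-hour visits for one pig
toy_visits <- function(n = 20, pig_id = "p1", seed = 1,
                       start = as.POSIXct("2020-12-15", tz = "UTC")) {
  set.seed(seed)
  hour_slots <- seq_len(n) - 1
  entry <- start + hour_slots * 3600 + 300
  dur <- runif(n, 120, 600)
  data.frame(pig_id = pig_id, pen_id = "penA",
             entry_ts = entry, exit_ts = entry + dur,
             intake_g = runif(n, 20, 120))
}
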