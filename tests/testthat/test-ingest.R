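start0 <- as.POSIXct("2020-12-15", tz = "UTC")

test_that("each cleaning rule removes exactly its labelled violation", {
  v <- toy_visits(n = 20)
  # inject one violation per rule family into known rows
  v$intake_g[3] <- -12                                   # r1 negative intake
  v$exit_ts[5] <- v$entry_ts[5] + 10                     # r2: rate spike
  v$intake_g[5] <- 500                                   # 3000 g/min
  v$exit_ts[20] <- v$entry_ts[20] + 7200                 # r3: 2 h visit
  out <- clean_visits(v, cleaning_rules(day_frac_max = NA), start_date = start0)
  expect_equal(unname(out$report$n_removed),
               c(1, 1, 1, 0, 0))
  expect_equal(nrow(out$visits), 17)
  expect_false(any(out$visits$intake_g < 0))
  # mass conservation of survivors
  expect_equal(sum(out$visits$intake_g),
               sum(v$intake_g[-c(3, 5, 20)]))
})

test_that("disabling all rules is the identity", {
  v <- toy_visits(n = 10)
  v$intake_g[2] <- -5
  out <- clean_visits(v, cleaning_rules(tol = NA, rate_max = NA, dur_max = NA,
                                        day_frac_max = NA, overlap = FALSE),
                      start_date = start0)
  expect_identical(out$visits, v)
  expect_equal(sum(out$report$n_removed), 0)
})

test_that("overlapping same-pig visits and bad pig-days are removed", {
  v <- toy_visits(n = 10)
  v$entry_ts[4] <- v$entry_ts[3] + 60 # starts inside visit 3
  v$exit_ts[4] <- v$entry_ts[4] + 120
  out <- clean_visits(v, cleaning_rules(day_frac_max = NA), start_date = start0)
  expect_equal(unname(out$report$n_removed[["overlap"]]), 1)

  # pig-day rule: 2 of 3 visits on one day corrupted -> whole day goes
  day2 <- start0 + 86400
  v2 <- data.frame(pig_id = "p1", pen_id = "A",
                   entry_ts = day2 + c(1, 2, 3, 30) * 3600,
                   exit_ts = day2 + c(1, 2, 3, 30) * 3600 + 300,
                   intake_g = c(-5, -8, 50, 60))
  out2 <- clean_visits(v2, cleaning_rules(day_frac_max = 0.25),
                       start_date = start0)
  expect_equal(unname(out2$report$n_removed[["pig_day"]]), 1)
  expect_equal(out2$report$n_pig_days_removed, 1)
  expect_equal(out2$removed_pig_days$day, 2)
  expect_equal(nrow(out2$visits), 1) # only the day-3 visit survives
})

test_that("synthetic corruption labels match cleaning decisions", {
  spec <- tiny_spec(n_days = 10, seed = 21)
  set.seed(21)
  s <- generate_hourly(profile_alternans(), spec)
  v <- generate_visits(s)
  set.seed(22)
  inj <- inject_errors(v, error_spec(0.03, 0.03, 0.03))
  out <- clean_visits(inj$visits, cleaning_rules(day_frac_max = NA),
                      start_date = start0)
  n_corrupt <- sum(inj$labels$label == "corrupted")
  expect_equal(sum(out$report$n_removed), n_corrupt)
  expect_equal(nrow(out$visits), nrow(v) - n_corrupt)
})

test_that("enabling additional rules never increases survivors", {
  v <- toy_visits(n = 50, seed = 9)
  v$intake_g[c(2, 9)] <- -4
  v$exit_ts[15] <- v$entry_ts[15] + 7300
  n_r1 <- nrow(clean_visits(v, cleaning_rules(rate_max = NA, dur_max = NA,
                                              day_frac_max = NA,
                                              overlap = FALSE),
                            start_date = start0)$visits)
  n_r13 <- nrow(clean_visits(v, cleaning_rules(rate_max = NA,
                                               day_frac_max = NA,
                                               overlap = FALSE),
                             start_date = start0)$visits)
  n_all <- nrow(clean_visits(v, cleaning_rules(), start_date = start0)$visits)
  expect_lte(n_r13, n_r1)
  expect_lte(n_all, n_r13)
})

test_that("unparseable records are quarantined, not dropped silently", {
  v <- toy_visits(n = 5)
  v$exit_ts[2] <- NA
  out <- clean_visits(v, cleaning_rules(), start_date = start0)
  expect_equal(out$report$n_quarantined, 1)
  expect_equal(nrow(out$visits) + 1 + sum(out$report$n_removed), 5)
})

test_that("welfare day filters remove the analytically enumerated set", {
  vals <- matrix(50, 60, 24)
  s <- hourly_series(vals, pig_id = "p1", pen_id = "A")
  ev <- data.frame(pig_id = c("p1", NA, NA),
                   event_type = c("disease", "first_obs", "slaughter"),
                   day = c(30, 5, 55))
  f <- filter_pig_days(s, ev)
  gone <- which(apply(f$missing_mask, 1, all))
  expect_equal(gone, sort(c(1:4, 27:33, 56:60)))
  # +-3 day window is inclusive at both ends
  expect_true(all(c(27, 33) %in% gone))
  expect_false(any(c(26, 34) %in% gone))
})

test_that("empty events leave the series unchanged; filters are idempotent", {
  vals <- matrix(50, 20, 24)
  s <- hourly_series(vals, pig_id = "p1", pen_id = "A")
  ev0 <- data.frame(pig_id = c(NA, NA), event_type = c("first_obs", "slaughter"),
                    day = c(1, 20))
  f0 <- filter_pig_days(s, ev0)
  expect_equal(sum(f0$missing_mask), 0)

  ev <- data.frame(pig_id = "p1", event_type = "disease", day = 10)
  f1 <- filter_pig_days(s, ev)
  f2 <- filter_pig_days(f1, ev)
  expect_identical(f1$missing_mask, f2$missing_mask)
  expect_identical(f1$values, f2$values)
})

test_that("events for unknown pigs warn but do not fail", {
  s <- hourly_series(matrix(10, 5, 24), pig_id = "p1", pen_id = "A")
  ev <- data.frame(pig_id = "ghost", event_type = "disease", day = 3)
  expect_warning(filter_pig_days(list(s), ev), "ghost")
})

test_that("hour-boundary-spanning visits split proportionally to time", {
  # 40 minutes in hour 10, 20 minutes in hour 11 -> 2/3 and 1/3 of 90 g
  v <- data.frame(pig_id = "p1", pen_id = "A",
                  entry_ts = start0 + 10 * 3600 + 20 * 60,
                  exit_ts = start0 + 11 * 3600 + 20 * 60,
                  intake_g = 90)
  agg <- aggregate_hourly(v, n_days = 1, start_date = start0)
  expect_equal(agg[["p1"]]$values[1, 11], 60)
  expect_equal(agg[["p1"]]$values[1, 12], 30)
  # within-hour visits sum into their bin; others are zero, not missing
  v2 <- rbind(v, data.frame(pig_id = "p1", pen_id = "A",
                            entry_ts = start0 + c(10.25, 10.66) * 3600,
                            exit_ts = start0 + c(10.3, 10.7) * 3600,
                            intake_g = c(50, 30)))
  agg2 <- aggregate_hourly(v2, n_days = 1, start_date = start0)
  expect_equal(agg2[["p1"]]$values[1, 11], 140)
  expect_equal(sum(agg2[["p1"]]$missing_mask), 0)
  expect_equal(sum(agg2[["p1"]]$values), 170)
})

test_that("removed pig-days surface as missing, not zero", {
  v <- toy_visits(n = 6)
  agg <- aggregate_hourly(v, n_days = 3,
                          removed_pig_days = data.frame(pig_id = "p1", day = 2))
  expect_true(all(agg[["p1"]]$missing_mask[2, ]))
  expect_false(any(agg[["p1"]]$missing_mask[c(1, 3), ]))
})
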