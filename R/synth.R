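#' Diurnal ground-truth profile for one synthetic animal
#'
#' A diurnal profile specifies, for each of the 24 hour bins, the probability
#' that the animal eats in that hour (`p_eat`) and the mean positive intake
#' conditional on eating (`mu_intake`, grams). `consistency` in `[0, 1]`
#' scales day-to-day jitter of the realised profile: 1 means the same profile
#' is replayed every day, 0 means heavy day-to-day distortion.
#'
#' @param pattern_kind one of `"alternans"`, `"single_peak"`,
#'   `"night_feeder"`, `"flat"`.
#' @param p_eat numeric length 24, hourly eating probabilities in `[0, 1]`.
#' @param mu_intake numeric length 24, mean positive hourly intake (g).
#' @param consistency scalar in `[0, 1]`.
#' @return object of class `diurnal_profile`.
#' @seealso [profile_alternans()], [generate_hourly()]
#' @export
diurnal_profile <- function(pattern_kind, p_eat, mu_intake, consistency = 0.9) {
  pattern_kind <- match.arg(pattern_kind,
                            c("alternans", "single_peak", "night_feeder", "flat"))
  if (length(p_eat) != 24L || length(mu_intake) != 24L)
    stop("'p_eat' and 'mu_intake' must have length exactly 24")
  if (any(p_eat < 0 | p_eat > 1)) stop("'p_eat' values must lie in [0, 1]")
  if (any(mu_intake < 0)) stop("'mu_intake' values must be >= 0")
  if (consistency < 0 || consistency > 1) stop("'consistency' must lie in [0, 1]")
  structure(list(pattern_kind = pattern_kind, p_eat = p_eat,
                 mu_intake = mu_intake, consistency = consistency),
            class = "diurnal_profile")
}

# circular gaussian bump centred at `centre` (hours), sd `width` hours
circ_bump <- function(hours, centre, width) {
  d <- pmin(abs(hours - centre), 24 - abs(hours - centre))
  exp(-d^2 / (2 * width^2))
}

#' Preset diurnal profiles
#'
#' Canonical feeding shapes used throughout the test-bench: the alternans
#' pattern (small morning peak near 10:00, larger afternoon peak near 16:00,
#' night fasting), a single afternoon peak, a night feeder whose intake is
#' concentrated between 21:00 and 05:00, and a flat/irregular profile with no
#' diurnal structure. Hourly magnitudes are scaled so that a realised day
#' totals roughly 1.5--2 kg before the growth trend is applied, the realistic
#' range for a growing-finishing pig.
#'
#' @param consistency day-to-day consistency in `[0, 1]`.
#' @return a [diurnal_profile()].
#' @export
profile_alternans <- function(consistency = 0.9) {
  h <- 0:23
  p <- 0.05 + 0.55 * circ_bump(h, 10, 1.5) + 0.85 * circ_bump(h, 16, 2.0)
  p[h >= 21 | h < 5] <- 0.03
  mu <- 60 + 60 * circ_bump(h, 10, 1.5) + 140 * circ_bump(h, 16, 2.2)
  diurnal_profile("alternans", pmin(p, 0.97), mu, consistency)
}

#' @rdname profile_alternans
#' @export
profile_single_peak <- function(consistency = 0.9) {
  h <- 0:23
  p <- 0.05 + 0.9 * circ_bump(h, 16, 2.5)
  p[h >= 21 | h < 5] <- 0.03
  mu <- 60 + 180 * circ_bump(h, 16, 2.5)
  diurnal_profile("single_peak", pmin(p, 0.97), mu, consistency)
}

#' @rdname profile_alternans
#' @export
profile_night_feeder <- function(consistency = 0.4) {
  h <- 0:23
  night <- h >= 21 | h < 5
  p <- ifelse(night, 0.45, 0.25)
  mu <- ifelse(night, 140, 90)
  diurnal_profile("night_feeder", p, mu, consistency)
}

#' @rdname profile_alternans
#' @export
profile_flat <- function(consistency = 0.3) {
  diurnal_profile("flat", rep(0.3, 24), rep(110, 24), consistency)
}

#' Synthetic cohort design
#'
#' Mirrors the study design the pipeline targets: pens of group-housed pigs
#' each feeding at one electronic station, monitored over a growing-finishing
#' phase during which daily intake roughly ramps up with growth.
#'
#' @param n_pens,pigs_per_pen,n_days cohort dimensions (defaults 10 pens of
#'   11 pigs over 83 days, the study design being emulated).
#' @param trend function mapping day (1..n_days) to a multiplicative intake
#'   factor; default linear ramp from 1.0 to 2.5, the growth-driven increase
#'   later removed by LOESS de-trending.
#' @param sigma_pig,sigma_pen SDs of pig- and pen-level Gaussian offsets
#'   applied on the logit scale of `p_eat` (and half that magnitude on the
#'   log scale of `mu_intake`).
#' @param ar1_rho correlation between a pig's consecutive period-level
#'   deviations, `|ar1_rho| < 1` (used by downstream feature simulations).
#' @param missing_day_prob probability an entire day is missing for a pig.
#' @param gamma_shape shape of the gamma draw for positive hourly intake.
#' @param seed integer RNG seed giving byte-reproducible cohorts.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_pens = 10L, pigs_per_pen = 11L, n_days = 83L,
                        trend = NULL, sigma_pig = 0.3, sigma_pen = 0.15,
                        ar1_rho = 0.3, missing_day_prob = 0.02,
                        gamma_shape = 4, seed = 1L) {
  if (n_pens < 1 || pigs_per_pen < 1 || n_days < 1) stop("counts must be >= 1")
  if (missing_day_prob < 0 || missing_day_prob > 1)
    stop("'missing_day_prob' must lie in [0, 1]")
  if (abs(ar1_rho) >= 1) stop("'ar1_rho' must satisfy |rho| < 1")
  if (is.null(trend)) {
    nd <- n_days
    trend <- function(day) 1 + 1.5 * (day - 1) / max(nd - 1, 1)
  }
  structure(list(n_pens = as.integer(n_pens),
                 pigs_per_pen = as.integer(pigs_per_pen),
                 n_days = as.integer(n_days), trend = trend,
                 sigma_pig = sigma_pig, sigma_pen = sigma_pen,
                 ar1_rho = ar1_rho, missing_day_prob = missing_day_prob,
                 gamma_shape = gamma_shape, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate one animal's hourly intake series from a diurnal profile
#'
#' For each hour of each day an eat/no-eat indicator is drawn from a
#' Bernoulli with the day-jittered `p_eat`, and positive intake from a gamma
#' distribution with mean `trend(day) * mu_intake[hour]` (day-jittered) and
#' shape `spec$gamma_shape`. Day-to-day jitter is Gaussian on the logit scale
#' of `p_eat` and the log scale of `mu_intake`, with SD scaled by
#' `(1 - consistency)` so a fully consistent animal replays its profile
#' exactly. Whole days are marked missing with probability
#' `spec$missing_day_prob`. The generating profile is attached as attribute
#' `"truth"` so downstream recovery tests can compare against ground truth.
#'
#' Uses the current RNG state; seed via `set.seed()` or [simulate_cohort()].
#'
#' @param profile a [diurnal_profile()].
#' @param spec a [cohort_spec()].
#' @param pig_index,pen_index identifiers used to label the series.
#' @param logit_offset,log_mu_offset animal/pen-level offsets applied to the
#'   logit of `p_eat` and the log of `mu_intake` (drawn by
#'   [simulate_cohort()] from `sigma_pig`/`sigma_pen`).
#' @param jitter_sd base jitter SDs, named `c(logit = 2, log = 0.8)`; the
#'   effective SD is `jitter_sd * (1 - consistency)`.
#' @return an [hourly_series()] with attribute `"truth"`.
#' @export
generate_hourly <- function(profile, spec, pig_index = 1L, pen_index = 1L,
                            logit_offset = 0, log_mu_offset = 0,
                            jitter_sd = c(logit = 2, log = 0.8)) {
  stopifnot(inherits(profile, "diurnal_profile"), inherits(spec, "cohort_spec"))
  n_days <- spec$n_days
  sd_logit <- jitter_sd[["logit"]] * (1 - profile$consistency)
  sd_log <- jitter_sd[["log"]] * (1 - profile$consistency)
  p0 <- qlogis(pmin(pmax(profile$p_eat, 1e-6), 1 - 1e-6)) + logit_offset
  values <- matrix(NA_real_, n_days, 24)
  missing <- rep(FALSE, n_days)
  for (d in seq_len(n_days)) {
    if (stats::runif(1) < spec$missing_day_prob) { missing[d] <- TRUE; next }
    p_day <- plogis(p0 + stats::rnorm(24, 0, sd_logit))
    # hours with p_eat exactly 0 or 1 stay deterministic
    p_day[profile$p_eat == 0] <- 0
    p_day[profile$p_eat == 1] <- 1
    mu_day <- spec$trend(d) * profile$mu_intake *
      exp(log_mu_offset + stats::rnorm(24, 0, sd_log))
    eat <- stats::rbinom(24, 1, p_day)
    intake <- numeric(24)
    pos <- eat == 1 & mu_day > 0
    if (any(pos))
      intake[pos] <- stats::rgamma(sum(pos), shape = spec$gamma_shape,
                                   rate = spec$gamma_shape / mu_day[pos])
    values[d, ] <- intake
  }
  mm <- matrix(missing, n_days, 24)
  series <- hourly_series(values, pig_id = pig_index, pen_id = pen_index,
                          missing_mask = mm)
  attr(series, "truth") <- list(profile = profile,
                                trend = vapply(seq_len(n_days), spec$trend, 0),
                                logit_offset = logit_offset,
                                log_mu_offset = log_mu_offset)
  series
}

#' Explode an hourly series into feeder-visit records
#'
#' Inverts the hourly aggregation: each non-zero hour is split into 1--3
#' visits whose intakes sum exactly to the hourly value (dyadic split
#' fractions 1, 1/2 + 1/2, or 1/2 + 1/4 + 1/4, which are exact in binary
#' floating point) and whose timestamps lie in disjoint sub-intervals of the
#' hour. Missing days produce no visits.
#'
#' @param hourly an [hourly_series()].
#' @param start_date POSIXct origin of day 1 (00:00).
#' @return data.frame with columns `pig_id`, `pen_id`, `entry_ts`, `exit_ts`,
#'   `intake_g`.
#' @export
generate_visits <- function(hourly,
                            start_date = as.POSIXct("2020-12-15", tz = "UTC")) {
  stopifnot(inherits(hourly, "hourly_series"))
  long <- hourly_long(hourly)
  long <- long[!long$missing & long$intake_g > 0, , drop = FALSE]
  if (nrow(long) == 0L)
    return(data.frame(pig_id = character(), pen_id = character(),
                      entry_ts = as.POSIXct(character(), tz = "UTC"),
                      exit_ts = as.POSIXct(character(), tz = "UTC"),
                      intake_g = numeric()))
  rows <- lapply(seq_len(nrow(long)), function(i) {
    x <- long$intake_g[i]
    k <- sample.int(3L, 1L)
    frac <- switch(k, c(1), c(0.5, 0.5), c(0.5, 0.25, 0.25))
    slot <- 3600 / k
    off <- (seq_len(k) - 1) * slot + stats::runif(k, 0, 0.2 * slot)
    dur <- pmin(x * frac / (stats::runif(k, 20, 40) / 60), 0.7 * slot)
    base <- as.numeric(start_date) + (long$day[i] - 1) * 86400 +
      long$hour[i] * 3600
    data.frame(pig_id = long$pig_id[i], pen_id = long$pen_id[i],
               entry_ts = as.POSIXct(base + off, tz = "UTC",
                                     origin = "1970-01-01"),
               exit_ts = as.POSIXct(base + off + dur, tz = "UTC",
                                    origin = "1970-01-01"),
               intake_g = x * frac)
  })
  out <- do.call(rbind, rows)
  out[order(out$entry_ts), , drop = FALSE]
}

#' Error-injection settings for synthetic visit records
#'
#' Per-visit probabilities of corrupting a record with a negative intake, an
#' implausibly fast feeding rate, or an implausibly long visit -- the three
#' signatures the visit-cleaning rules target.
#'
#' @param neg_intake_rate,rate_spike_rate,long_visit_rate probabilities in
#'   `[0, 1]`.
#' @return object of class `error_spec`.
#' @export
error_spec <- function(neg_intake_rate = 0, rate_spike_rate = 0,
                       long_visit_rate = 0) {
  r <- c(neg_intake_rate, rate_spike_rate, long_visit_rate)
  if (any(r < 0 | r > 1)) stop("all rates must lie in [0, 1]")
  structure(list(neg_intake_rate = neg_intake_rate,
                 rate_spike_rate = rate_spike_rate,
                 long_visit_rate = long_visit_rate),
            class = "error_spec")
}

#' Inject recording errors into visit records
#'
#' Each visit is independently corrupted with the configured per-type
#' probabilities (a visit can receive several corruption types; it is then
#' labelled once as corrupted). Corruptions are constructed to violate the
#' default cleaning thresholds: negative intake, feeding rate of 300 g/min,
#' or visit duration of 2 hours.
#'
#' @param visits visit data.frame as produced by [generate_visits()].
#' @param err an [error_spec()].
#' @return list with `visits` (corrupted table) and `labels` (data.frame with
#'   `label` in `{"clean", "corrupted"}` and logical per-type flags).
#' @export
inject_errors <- function(visits, err) {
  stopifnot(inherits(err, "error_spec"))
  n <- nrow(visits)
  neg <- stats::runif(n) < err$neg_intake_rate
  spike <- stats::runif(n) < err$rate_spike_rate
  long <- stats::runif(n) < err$long_visit_rate
  v <- visits
  if (any(neg)) v$intake_g[neg] <- -abs(v$intake_g[neg]) - stats::runif(sum(neg), 1, 50)
  if (any(spike)) # compress duration so the rate is ~300 g/min
    v$exit_ts[spike] <- v$entry_ts[spike] +
      pmax(abs(v$intake_g[spike]) / 300 * 60, 0.5)
  if (any(long)) v$exit_ts[long] <- v$entry_ts[long] + 7200 +
      stats::runif(sum(long), 0, 3600)
  labels <- data.frame(
    label = ifelse(neg | spike | long, "corrupted", "clean"),
    neg_intake = neg, rate_spike = spike, long_visit = long)
  list(visits = v, labels = labels)
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Draws pen- and pig-level offsets, generates each animal's hourly series
#' from its assigned diurnal profile, and explodes the series into visit
#' records. Setting `spec$seed` makes the whole cohort byte-reproducible.
#'
#' @param spec a [cohort_spec()].
#' @param profiles list of [diurnal_profile()] objects assigned to pigs in
#'   round-robin order, or a function `(pig, pen) -> profile`.
#' @param start_date POSIXct origin of day 1.
#' @return list with `hourly` (list of [hourly_series()], each carrying its
#'   `"truth"` attribute), `visits` (one combined data.frame), `pigs`
#'   (data.frame of pig/pen ids and profile kinds), and `spec`.
#' @export
simulate_cohort <- function(spec, profiles = list(profile_alternans()),
                            start_date = as.POSIXct("2020-12-15", tz = "UTC")) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_pigs <- spec$n_pens * spec$pigs_per_pen
  pen_off <- stats::rnorm(spec$n_pens, 0, spec$sigma_pen)
  pig_off <- stats::rnorm(n_pigs, 0, spec$sigma_pig)
  hourly <- vector("list", n_pigs)
  pigs <- data.frame(pig_id = character(n_pigs), pen_id = character(n_pigs),
                     pattern_kind = character(n_pigs))
  visits <- vector("list", n_pigs)
  for (i in seq_len(n_pigs)) {
    pen <- (i - 1) %/% spec$pigs_per_pen + 1L
    pig_id <- sprintf("pig%03d", i)
    pen_id <- sprintf("pen%02d", pen)
    prof <- if (is.function(profiles)) profiles(i, pen)
            else profiles[[(i - 1) %% length(profiles) + 1L]]
    s <- generate_hourly(prof, spec, pig_index = pig_id, pen_index = pen_id,
                         logit_offset = pen_off[pen] + pig_off[i],
                         log_mu_offset = 0.5 * (pen_off[pen] + pig_off[i]))
    hourly[[i]] <- s
    pigs$pig_id[i] <- pig_id; pigs$pen_id[i] <- pen_id
    pigs$pattern_kind[i] <- prof$pattern_kind
    visits[[i]] <- generate_visits(s, start_date = start_date)
  }
  list(hourly = hourly, visits = do.call(rbind, visits), pigs = pigs,
       spec = spec)
}

#' Simulate a pig-period feature table with known variance components
#'
#' Generates one feature value per pig-period as the sum of fixed period
#' effects, a pen-level intercept, a pig-level intercept and an AR(1)
#' process across consecutive periods within pig -- exactly the generative
#' model assumed by [fit_period_model()], so recovered variance components
#' and intraclass correlations can be checked against truth.
#'
#' @param n_pens,pigs_per_pen,n_periods design dimensions.
#' @param var_pig,var_pen,var_resid true variance components (the residual
#'   is the stationary AR(1) variance).
#' @param rho AR(1) correlation between consecutive periods.
#' @param period_effects fixed effect per period (length `n_periods`).
#' @param seed optional seed (uses current RNG state when `NULL`).
#' @return data.frame `value`, `period_id`, `pen_id`, `pig_id`.
#' @export
simulate_feature_table <- function(n_pens = 10, pigs_per_pen = 11,
                                   n_periods = 5, var_pig = 1,
                                   var_pen = 0.25, var_resid = 0.75,
                                   rho = 0.3,
                                   period_effects = rep(0, n_periods),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_pigs <- n_pens * pigs_per_pen
  pen_of <- rep(seq_len(n_pens), each = pigs_per_pen)
  b_pen <- stats::rnorm(n_pens, 0, sqrt(var_pen))
  b_pig <- stats::rnorm(n_pigs, 0, sqrt(var_pig))
  rows <- lapply(seq_len(n_pigs), function(i) {
    z <- numeric(n_periods)
    z[1] <- stats::rnorm(1, 0, sqrt(var_resid))
    for (t in seq_len(n_periods)[-1])
      z[t] <- rho * z[t - 1] +
        stats::rnorm(1, 0, sqrt(var_resid * (1 - rho^2)))
    data.frame(value = period_effects + b_pen[pen_of[i]] + b_pig[i] + z,
               period_id = seq_len(n_periods),
               pen_id = sprintf("pen%02d", pen_of[i]),
               pig_id = sprintf("pig%03d", i))
  })
  do.call(rbind, rows)
}

#' Write synthetic visits and ground truth to disk
#'
#' Visits go to CSV (ISO-8601 timestamps); the generating profiles to a JSON
#' sidecar.
#'
#' @param cohort result of [simulate_cohort()].
#' @param visits_path,truth_path output file paths.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, visits_path, truth_path = NULL) {
  v <- cohort$visits
  v$entry_ts <- format(v$entry_ts, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  v$exit_ts <- format(v$exit_ts, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  utils::write.csv(v, visits_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    truth <- lapply(cohort$hourly, function(s) {
      tr <- attr(s, "truth")
      list(pig_id = s$pig_id, pen_id = s$pen_id,
           pattern_kind = tr$profile$pattern_kind,
           p_eat = tr$profile$p_eat, mu_intake = tr$profile$mu_intake,
           consistency = tr$profile$consistency)
    })
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(visits_path, truth_path))
}
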