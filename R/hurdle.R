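#' Partition the study window into modelling periods
#'
#' Consecutive `period_len`-day blocks from the first retained cohort day;
#' the final partial block is kept as its own (shorter) period. With the
#' default 14-day blocks on a day-5 to day-83 window this yields the period
#' layout days 5--18, 19--32, 33--46, 47--60, 61--74 and a short final
#' period 75--83.
#'
#' @param day_range integer vector `c(first, last)` cohort day, or an
#'   [hourly_series()] whose `day_index` range is used.
#' @param period_len block length in days.
#' @return data.frame of class `period_definition`: `period_id`,
#'   `day_start`, `day_end`, `n_days`.
#' @export
assign_periods <- function(day_range, period_len = 14L) {
  if (inherits(day_range, "hourly_series"))
    day_range <- range(day_range$day_index)
  first <- day_range[1]; last <- day_range[2]
  starts <- seq(first, last, by = period_len)
  ends <- pmin(starts + period_len - 1L, last)
  structure(data.frame(period_id = seq_along(starts), day_start = starts,
                       day_end = ends, n_days = ends - starts + 1L),
            class = c("period_definition", "data.frame"))
}

# map day numbers to period ids (NA outside all periods)
match_period <- function(day, periods) {
  out <- rep(NA_integer_, length(day))
  for (i in seq_len(nrow(periods)))
    out[day >= periods$day_start[i] & day <= periods$day_end[i]] <-
      periods$period_id[i]
  out
}

#' Per-pig period availability
#'
#' Counts non-missing days per period and flags pig-periods retained under
#' the minimum-availability rule (default: at least 7 of the 14 days).
#'
#' @param series an [hourly_series()].
#' @param periods a [assign_periods()] table.
#' @param min_days minimum available days for a pig-period to be retained.
#' @return the period table with `n_available_days` and `retained` columns.
#' @export
period_availability <- function(series, periods, min_days = 7L) {
  whole_day_ok <- !apply(series$missing_mask, 1L, all)
  pd <- match_period(series$day_index, periods)
  av <- vapply(periods$period_id,
               function(p) sum(whole_day_ok & pd %in% p), 0L)
  periods$n_available_days <- av
  periods$retained <- av >= min_days
  periods
}

# model data for one pig: one row per retained, non-missing hour
hurdle_data <- function(series, periods) {
  long <- hourly_long(series)
  long$period_id <- match_period(long$day, periods)
  ret <- periods$period_id[periods$retained]
  d <- long[!long$missing & long$period_id %in% ret, , drop = FALSE]
  d$hour_mid <- d$hour + 0.5 # covariate at the bin midpoint
  d$period <- factor(d$period_id, levels = ret)
  d$eat <- as.integer(d$intake_g > 0)
  d
}

#' Fit the two-part (hurdle) diurnal GAM for one animal
#'
#' The hurdle decomposition of a zero-adjusted gamma model: part A fits the
#' binary eat indicator per hour (binomial, logit link) and part B the
#' positive intakes (gamma, log link), each with a cyclic cubic diurnal
#' spline in hour (8 knots on `[0, 24]`, one smooth per retained period) plus
#' a P-spline trend in day (4 knots). The two likelihood factors share no
#' parameters, so the total log-likelihood is the sum of the parts and the
#' parts can be maximised independently. Smooths are fixed-df regression
#' splines by default, which makes nested likelihood-ratio comparisons
#' behave like classical chi-squared tests; set `penalized = TRUE` for
#' REML-selected smoothing parameters instead.
#'
#' Degenerate data are handled explicitly: an animal that eats in every
#' retained hour gets a trivial probability part (`pi == 1`, log-likelihood
#' 0); a period with no positive intakes leaves the intake part undefined
#' there (flagged in `sigma_by_period`).
#'
#' @param series an [hourly_series()].
#' @param periods period table; defaults to [assign_periods()] over the
#'   series' day range, with availability filtering at `min_days`.
#' @param knots_hour,knots_day basis dimensions of the cyclic hour smooth
#'   and the day trend smooth.
#' @param diurnal `"by_period"` (full model), `"single"` (one diurnal shape
#'   for all periods) or `"none"` (trend only) -- the reduced forms used in
#'   likelihood-ratio comparisons.
#' @param min_days availability threshold per pig-period.
#' @param penalized logical; penalised (REML) instead of fixed-df smooths.
#' @return object of class `hurdle_fit`: fitted parts `prob_gam` /
#'   `intake_gam`, `loglik`, `edf`, `sigma_by_period` (per-period gamma
#'   dispersion of part B), `periods`, `data`, and flags.
#' @export
fit_hurdle <- function(series, periods = NULL, knots_hour = 8L, knots_day = 4L,
                       diurnal = c("by_period", "single", "none"),
                       min_days = 7L, penalized = FALSE) {
  diurnal <- match.arg(diurnal)
  stopifnot(inherits(series, "hourly_series"))
  if (is.null(periods))
    periods <- assign_periods(range(series$day_index))
  if (!"retained" %in% names(periods))
    periods <- period_availability(series, periods, min_days)
  if (!any(periods$retained)) stop("no retained period for this pig")
  d <- hurdle_data(series, periods)
  if (!nrow(d)) stop("no usable hours for this pig")
  kn <- list(hour_mid = seq(0, 24, length.out = knots_hour))
  fx <- !penalized
  method <- if (penalized) "REML" else "GCV.Cp"
  n_per <- length(levels(d$period))
  hour_term <- switch(diurnal,
    by_period = if (n_per > 1)
      sprintf("s(hour_mid, bs='cc', k=%d, by=period, fx=%s)", knots_hour, fx)
    else sprintf("s(hour_mid, bs='cc', k=%d, fx=%s)", knots_hour, fx),
    single = sprintf("s(hour_mid, bs='cc', k=%d, fx=%s)", knots_hour, fx),
    none = NULL)
  day_term <- sprintf("s(day, bs='ps', k=%d, fx=%s)", knots_day, fx)
  rhs <- paste(c(hour_term, day_term), collapse = " + ")

  # part A: probability of eating
  prob_trivial <- all(d$eat == 1L)
  if (prob_trivial) {
    prob_gam <- NULL; ll_a <- 0; edf_a <- 0
  } else {
    prob_gam <- mgcv::gam(stats::as.formula(paste("eat ~", rhs)),
                          family = stats::binomial(), data = d, knots = kn,
                          method = method)
    ll_a <- as.numeric(stats::logLik(prob_gam)); edf_a <- sum(prob_gam$edf) + 1
  }
  # part B: positive intakes
  pos <- d[d$eat == 1L, , drop = FALSE]
  if (!nrow(pos)) stop("no positive intakes; intake part cannot be fitted")
  pos$period <- droplevels(pos$period)
  rhs_b <- rhs
  if (diurnal == "by_period" && nlevels(pos$period) < 2)
    rhs_b <- paste(c(sprintf("s(hour_mid, bs='cc', k=%d, fx=%s)", knots_hour, fx),
                     day_term), collapse = " + ")
  intake_gam <- mgcv::gam(stats::as.formula(paste("intake_g ~", rhs_b)),
                          family = stats::Gamma(link = "log"), data = pos,
                          knots = kn, method = method)
  ll_b <- as.numeric(stats::logLik(intake_gam))
  edf_b <- sum(intake_gam$edf) + 1 # + scale parameter

  # per-period gamma dispersion of part B (method of moments on Pearson
  # residuals, the per-period analogue of the single gam scale)
  mu_hat <- stats::fitted(intake_gam)
  pr2 <- ((pos$intake_g - mu_hat) / mu_hat)^2
  sigma_by_period <- tapply(pr2, pos$period, mean)

  structure(list(prob_gam = prob_gam, intake_gam = intake_gam,
                 prob_trivial = prob_trivial,
                 loglik = ll_a + ll_b, loglik_parts = c(prob = ll_a, intake = ll_b),
                 edf = edf_a + edf_b,
                 sigma_by_period = sigma_by_period,
                 periods = periods, data = d, diurnal = diurnal,
                 knots = c(hour = knots_hour, day = knots_day),
                 pig_id = series$pig_id, pen_id = series$pen_id),
            class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("<hurdle_fit> pig %s: %d retained periods, logLik %.1f (edf %.1f)\n",
              x$pig_id, sum(x$periods$retained), x$loglik, x$edf))
  invisible(x)
}

#' Predict from a fitted hurdle model
#'
#' Evaluates the probability-of-eating surface `pi(hour, day)`, the positive
#' intake surface `mu(hour, day)` (g) and their product, the predicted
#' intake -- the hurdle identity `predicted = pi * mu` holds exactly by
#' construction.
#'
#' @param fit a [fit_hurdle()] object.
#' @param hours numeric vector of hours in `[0, 24)`.
#' @param days numeric vector of day numbers (recycled against `hours` via
#'   expansion: the returned grid is all `hours x days` combinations).
#' @return data.frame `hour`, `day`, `period`, `prob`, `mu`,
#'   `predicted_intake`.
#' @export
predict_hurdle <- function(fit, hours, days) {
  stopifnot(inherits(fit, "hurdle_fit"))
  grid <- expand.grid(hour_mid = hours, day = days)
  grid$period_id <- match_period(grid$day, fit$periods)
  grid$period <- factor(grid$period_id, levels = levels(fit$data$period))
  ok <- !is.na(grid$period)
  prob <- rep(NA_real_, nrow(grid)); mu <- rep(NA_real_, nrow(grid))
  if (fit$prob_trivial) prob[ok] <- 1
  else prob[ok] <- stats::predict(fit$prob_gam, newdata = grid[ok, ],
                                  type = "response")
  mu[ok] <- stats::predict(fit$intake_gam, newdata = grid[ok, ],
                           type = "response")
  data.frame(hour = grid$hour_mid, day = grid$day, period = grid$period_id,
             prob = prob, mu = mu, predicted_intake = prob * mu)
}

#' Likelihood-ratio comparison of nested hurdle fits
#'
#' `statistic = 2 * (loglik_full - loglik_reduced)`, degrees of freedom the
#' effective-df difference rounded to 2 decimals, p-value from the
#' chi-squared distribution. Both fits must use identical data (checked via
#' row counts); non-nested comparisons are refused. Statistics that come out
#' (numerically) negative are clamped to zero.
#'
#' @param full,reduced [fit_hurdle()] objects on the same data, `reduced`
#'   with a simpler diurnal structure.
#' @return data.frame `statistic`, `df`, `p`.
#' @export
lr_compare <- function(full, reduced) {
  stopifnot(inherits(full, "hurdle_fit"), inherits(reduced, "hurdle_fit"))
  if (nrow(full$data) != nrow(reduced$data) ||
      !identical(full$data$intake_g, reduced$data$intake_g))
    stop("fits are not nested: they use different data")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- round(full$edf - reduced$edf, 2)
  p <- if (df <= 0) as.numeric(stat <= 0) * 1 else
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  if (df <= 0 && stat > 0) p <- 0 # should not occur for properly nested fits
  if (stat == 0) p <- 1
  data.frame(statistic = stat, df = df, p = p)
}
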