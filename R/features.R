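#' De-trended diurnal prediction curve for one period
#'
#' Evaluates the predicted-intake surface on a fine hour grid (default step
#' 0.1 h) with the day-trend contribution held at its mean over the period's
#' days, yielding the de-trended diurnal curve in g/h that makes periods
#' comparable regardless of growth stage. Works on the link scales: the
#' trend spline term of each part is replaced by its period mean before the
#' inverse link and the hurdle product.
#'
#' @param fit a [fit_hurdle()] object.
#' @param period_id a retained period id.
#' @param step hour-grid step (h).
#' @return data.frame `hour`, `prob`, `mu`, `f` (de-trended predicted intake
#'   `prob * mu`, g/h).
#' @export
detrend_prediction <- function(fit, period_id, step = 0.1) {
  stopifnot(inherits(fit, "hurdle_fit"))
  per <- fit$periods
  if (!period_id %in% per$period_id[per$retained])
    stop("period ", period_id, " is not retained for this pig")
  days <- seq(per$day_start[per$period_id == period_id],
              per$day_end[per$period_id == period_id])
  days <- intersect(days, unique(fit$data$day)) # available days only
  hours <- seq(0, 24 - step, by = step)
  grid <- data.frame(hour_mid = hours,
                     day = mean(days), # placeholder, replaced termwise
                     period = factor(period_id,
                                     levels = levels(fit$data$period)))
  eta_part <- function(gam_fit) {
    if (is.null(gam_fit)) return(rep(Inf, length(hours))) # trivial prob part
    tr <- stats::predict(gam_fit, newdata = grid, type = "terms")
    day_col <- grep("s\\(day", colnames(tr))
    hour_cols <- setdiff(seq_len(ncol(tr)), day_col)
    # trend term averaged over the period's available days
    tgrid <- data.frame(hour_mid = 12, day = days,
                        period = factor(period_id,
                                        levels = levels(fit$data$period)))
    ttr <- stats::predict(gam_fit, newdata = tgrid, type = "terms")
    trend_mean <- mean(ttr[, day_col])
    rowSums(tr[, hour_cols, drop = FALSE]) + trend_mean +
      attr(tr, "constant")
  }
  prob <- stats::plogis(eta_part(fit$prob_gam))
  mu <- exp(eta_part(fit$intake_gam))
  data.frame(hour = hours, prob = prob, mu = mu, f = prob * mu)
}

# cyclic peak count: sign changes of the first difference from + to -,
# with plateaus attributed to their first point
count_peaks_cyclic <- function(f) {
  d <- diff(c(f, f[1]))
  s <- sign(d)
  # carry the *next* non-zero sign backwards through zero runs so a plateau
  # top counts once, at its first point
  nz <- which(s != 0)
  if (!length(nz)) return(0L) # constant curve: no peaks
  s_filled <- s
  idx <- seq_along(s)
  nxt <- vapply(idx, function(i) {
    j <- nz[nz >= i]
    if (length(j)) s[j[1]] else s[nz[1]]
  }, 0)
  s_filled[s == 0] <- nxt[s == 0]
  s_prev <- c(s_filled[length(s_filled)], s_filled[-length(s_filled)])
  sum(s_prev > 0 & s_filled < 0)
}

# trapezoidal integral of a cyclic curve over an hour window [a, b) mod 24
integrate_cyclic <- function(hour, f, a, b) {
  h <- c(hour, 24); y <- c(f, f[1]) # close the cycle
  inwin <- if (a < b) h >= a & h <= b else h >= a | h <= b
  if (a < b) {
    pracma::trapz(h[inwin], y[inwin])
  } else {
    pracma::trapz(h[h >= a], y[h >= a]) + pracma::trapz(h[h <= b], y[h <= b])
  }
}

#' Extract diurnal-pattern features from a prediction curve
#'
#' The six curve features plus the two day-to-day consistency features:
#' number of peaks (derivative sign changes from increasing to decreasing,
#' cyclic across midnight), timing and height of the highest peak, peak
#' width as the mean drop in height half an hour before and after the peak
#' (larger = narrower), the lowest intake, the proportion of predicted
#' intake obtained at night (21:00--05:00, trapezoidal integration of the
#' continuous curve, or hour-bin sums with `night_mode = "bins"`), and the
#' minimum and maximum of the eating-probability curve.
#'
#' @param curve data.frame `hour`, `f`, and optionally `prob`, as from
#'   [detrend_prediction()].
#' @param prob_range optional `c(min, max)` of the probability surface
#'   evaluated over the full hour-by-day grid (overrides the curve's own
#'   probability extremes).
#' @param night `c(start, end)` night window in hours (spanning midnight).
#' @param night_mode `"trapezoid"` or `"bins"`.
#' @return one-row data.frame with `n_peaks`, `peak_time_h`, `peak_height`,
#'   `peak_width`, `lowest_intake`, `night_prop`, `min_prob_eat`,
#'   `max_prob_eat`.
#' @export
extract_features <- function(curve, prob_range = NULL, night = c(21, 5),
                             night_mode = c("trapezoid", "bins")) {
  night_mode <- match.arg(night_mode)
  hour <- curve$hour; f <- curve$f
  if (any(!is.finite(f))) stop("non-finite values in the prediction curve")
  step <- hour[2] - hour[1]
  n <- length(f)
  i_max <- which.max(f)
  k <- round(0.5 / step) # half an hour in grid steps, cyclic
  lo <- ((i_max - 1 - k) %% n) + 1
  hi <- ((i_max - 1 + k) %% n) + 1
  width <- ((f[i_max] - f[lo]) + (f[i_max] - f[hi])) / 2
  night_prop <- if (night_mode == "trapezoid") {
    tot <- integrate_cyclic(hour, f, 0, 24)
    if (tot > 0) integrate_cyclic(hour, f, night[1], night[2]) / tot else NA_real_
  } else {
    inwin <- hour >= night[1] | hour < night[2]
    if (sum(f) > 0) sum(f[inwin]) / sum(f) else NA_real_
  }
  pr <- if (!is.null(prob_range)) prob_range
        else if (!is.null(curve$prob)) range(curve$prob) else c(NA, NA)
  data.frame(n_peaks = count_peaks_cyclic(f),
             peak_time_h = hour[i_max],
             peak_height = f[i_max],
             peak_width = width,
             lowest_intake = min(f),
             night_prop = night_prop,
             min_prob_eat = pr[1], max_prob_eat = pr[2])
}

#' Feature table for all retained periods of one fitted animal
#'
#' Runs [detrend_prediction()] and [extract_features()] per retained period.
#' The probability extremes are taken over the full hour-by-day surface of
#' the period (step `step` in hour, every available day), matching their
#' interpretation as day-to-day consistency of eating times.
#'
#' @param fit a [fit_hurdle()] object.
#' @param step hour-grid step.
#' @param night,night_mode passed to [extract_features()].
#' @return data.frame, one row per retained period, with `pig_id`, `pen_id`,
#'   `period_id` and the eight features.
#' @export
diurnal_features <- function(fit, step = 0.1, night = c(21, 5),
                             night_mode = "trapezoid") {
  stopifnot(inherits(fit, "hurdle_fit"))
  ret <- fit$periods[fit$periods$retained, ]
  rows <- lapply(ret$period_id, function(p) {
    curve <- detrend_prediction(fit, p, step = step)
    days <- intersect(seq(ret$day_start[ret$period_id == p],
                          ret$day_end[ret$period_id == p]),
                      unique(fit$data$day))
    surf <- predict_hurdle(fit, hours = seq(0, 24 - step, by = step),
                           days = days)
    feats <- extract_features(curve, prob_range = range(surf$prob),
                              night = night, night_mode = night_mode)
    cbind(pig_id = fit$pig_id, pen_id = fit$pen_id, period_id = p, feats)
  })
  do.call(rbind, rows)
}

#' Join the circadian-rhythm proportion onto the feature table
#'
#' Left join on (pig, period): each feature row gains
#' `prop_circadian_days`, the per-period proportion of circadian days from
#' the wavelet stage; rows whose pig-period lacks a (>= 7 evaluable days)
#' summary stay `NA` and drop out of downstream correlations.
#'
#' @param features feature table from [diurnal_features()] (possibly
#'   row-bound across pigs).
#' @param rhythm per-period rhythm summary from
#'   [summarise_rhythm()] with a `pig_id` column.
#' @return the feature table with a `prop_circadian_days` column.
#' @export
join_circadian <- function(features, rhythm) {
  key_f <- paste(features$pig_id, features$period_id)
  key_r <- paste(rhythm$pig_id, rhythm$group)
  features$prop_circadian_days <-
    rhythm$proportion_circadian[match(key_f, key_r)]
  features
}
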