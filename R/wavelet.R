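#' Log2-spaced period grid for the continuous wavelet transform
#'
#' Periods `lo * 2^(k/voices)` covering `[lo, hi]` hours; the upper endpoint
#' is appended if the dyadic grid stops short of it. With the default 20
#' voices per octave at least one grid row falls inside the circadian call
#' band 23.5--24.5 h.
#'
#' @param lo,hi period range in hours.
#' @param voices voices (sub-octaves) per octave.
#' @return strictly increasing numeric vector of periods (hours).
#' @export
wavelet_periods <- function(lo = 8, hi = 48, voices = 20) {
  p <- lo * 2^(seq(0, log2(hi / lo), by = 1 / voices))
  if (max(p) < hi) p <- c(p, hi)
  p
}

# period = fourier_factor * scale for the Morlet wavelet
morlet_fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Morlet continuous wavelet transform of an hourly series
#'
#' Computes the continuous wavelet transform with the analytic Morlet mother
#' wavelet (central frequency `omega0 = 6`), sampling interval 1 h, at the
#' given period grid. The default implementation multiplies in the frequency
#' domain after zero-padding well past the widest wavelet's support (so no
#' wrap-around leaks into the series); `method = "direct"` evaluates the
#' same transform by explicit time-domain convolution and exists as a slow
#' independent cross-check. Power is the squared modulus normalised by the
#' series variance, making it invariant to rescaling the input. The cone of
#' influence marks points closer to a series edge than the e-folding time
#' `sqrt(2) * scale`, where edge effects make power unreliable.
#'
#' @param x a `detrended_series` from [prepare_series()] or a numeric vector.
#' @param periods period grid in hours, see [wavelet_periods()].
#' @param omega0 Morlet central frequency.
#' @param method `"fft"` (frequency-domain, fast) or `"direct"`
#'   (time-domain convolution, oracle).
#' @return object of class `wavelet_spectrum`: `power`
#'   (`n_periods x n_time`), `periods_h`, `coi_ok` (TRUE where *outside* the
#'   cone of influence, i.e. edge-safe), `ridge` (per-timepoint period of
#'   maximal power), `fill_mask`, `pvals` (`NULL` until
#'   [surrogate_pvalues()]).
#' @export
morlet_cwt <- function(x, periods = wavelet_periods(), omega0 = 6,
                       method = c("fft", "direct")) {
  method <- match.arg(method)
  if (inherits(x, "detrended_series")) {
    fill <- x$fill_mask; pid <- x$pig_id; x <- x$values
  } else { fill <- rep(FALSE, length(x)); pid <- NA }
  if (any(diff(periods) <= 0)) stop("'periods' must be strictly increasing")
  N <- length(x)
  if (N < 2 * max(periods))
    warning("series shorter than twice the longest period; ",
            "long-period power is mostly inside the cone of influence")
  if (N < max(periods))
    stop("series shorter than the longest analysed period")
  v <- stats::var(x)
  if (v == 0) v <- 1 # constant series: power is exactly zero anyway
  xc <- x - mean(x)
  scales <- periods / morlet_fourier_factor(omega0)
  W <- if (method == "fft") cwt_fft(xc, scales, omega0)
       else cwt_direct(xc, scales, omega0)
  power <- Mod(W)^2 / v
  coi_ok <- outer(scales, seq_len(N), function(s, t)
    (t - 1) >= sqrt(2) * s & (N - t) >= sqrt(2) * s)
  ridge <- periods[max.col(t(power), ties.method = "first")]
  structure(list(power = power, periods_h = periods, pvals = NULL,
                 coi_ok = coi_ok, ridge = ridge, fill_mask = fill,
                 omega0 = omega0, pig_id = pid, n_time = N),
            class = "wavelet_spectrum")
}

# frequency-domain CWT (Torrence & Compo normalisation, dt = 1)
cwt_fft <- function(xc, scales, omega0) {
  N <- length(xc)
  npad <- 2^ceiling(log2(N + 8 * max(scales)))
  xh <- stats::fft(c(xc, rep(0, npad - N)))
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / npad, -2 * pi * (npad - k) / npad)
  W <- matrix(0 + 0i, length(scales), N)
  for (j in seq_along(scales)) {
    s <- scales[j]
    daughter <- pi^(-0.25) * sqrt(2 * pi * s) *
      exp(-(s * omega - omega0)^2 / 2) * (omega > 0)
    W[j, ] <- stats::fft(xh * daughter, inverse = TRUE)[1:N] / npad
  }
  W
}

# brute-force time-domain convolution; O(N^2) per scale, oracle only
cwt_direct <- function(xc, scales, omega0) {
  N <- length(xc)
  W <- matrix(0 + 0i, length(scales), N)
  for (j in seq_along(scales)) {
    s <- scales[j]
    for (n in seq_len(N)) {
      eta <- (seq_len(N) - n) / s
      W[j, n] <- sum(xc * sqrt(1 / s) * pi^(-0.25) *
                       exp(-1i * omega0 * eta) * exp(-eta^2 / 2))
    }
  }
  W
}

# internal fast path reused for surrogates: precompute daughters once
cwt_plan <- function(N, periods, omega0 = 6) {
  scales <- periods / morlet_fourier_factor(omega0)
  npad <- 2^ceiling(log2(N + 8 * max(scales)))
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / npad, -2 * pi * (npad - k) / npad)
  daughters <- matrix(0, length(scales), npad)
  for (j in seq_along(scales))
    daughters[j, ] <- pi^(-0.25) * sqrt(2 * pi * scales[j]) *
      exp(-(scales[j] * omega - omega0)^2 / 2) * (omega > 0)
  list(N = N, npad = npad, daughters = daughters)
}

cwt_power_planned <- function(x, plan) {
  xc <- x - mean(x)
  v <- stats::var(x); if (v == 0) v <- 1
  xh <- stats::fft(c(xc, rep(0, plan$npad - plan$N)))
  P <- matrix(0, nrow(plan$daughters), plan$N)
  for (j in seq_len(nrow(plan$daughters)))
    P[j, ] <- Mod(stats::fft(xh * plan$daughters[j, ],
                             inverse = TRUE)[1:plan$N] / plan$npad)^2
  P / v
}

#' Pointwise surrogate significance of wavelet power
#'
#' Simulates `n_sim` Gaussian white-noise series matched in length (and,
#' after variance normalisation, trivially in variance) to the observed
#' series, transforms each with the identical Morlet analysis, and assigns
#' each (time, period) pixel the p-value
#' `(1 + #\{simulations with power >= observed\}) / (n_sim + 1)` -- a valid
#' finite-sample p-value that can never be exactly zero. Several spectra of
#' equal length can share one surrogate ensemble via the list interface,
#' which amortises the simulation cost across animals.
#'
#' @param spectrum a `wavelet_spectrum`, or a list of them with equal
#'   `n_time` (one shared ensemble).
#' @param n_sim number of white-noise surrogates (>= 100).
#' @param seed integer seed for the surrogate ensemble.
#' @return the input with `pvals` filled in (same shape as `power`).
#' @export
surrogate_pvalues <- function(spectrum, n_sim = 1000, seed = 1L) {
  single <- inherits(spectrum, "wavelet_spectrum")
  specs <- if (single) list(spectrum) else spectrum
  stopifnot(all(vapply(specs, inherits, TRUE, "wavelet_spectrum")))
  if (n_sim < 100) stop("'n_sim' must be >= 100")
  N <- unique(vapply(specs, function(s) s$n_time, 0L))
  if (length(N) != 1L)
    stop("all spectra must have the same length to share an ensemble")
  periods <- specs[[1]]$periods_h
  omega0 <- specs[[1]]$omega0
  plan <- cwt_plan(N, periods, omega0)
  counts <- lapply(specs, function(s) matrix(0, nrow(s$power), ncol(s$power)))
  set.seed(seed)
  for (i in seq_len(n_sim)) {
    Ps <- cwt_power_planned(stats::rnorm(N), plan)
    for (j in seq_along(specs))
      counts[[j]] <- counts[[j]] + (Ps >= specs[[j]]$power)
  }
  for (j in seq_along(specs))
    specs[[j]]$pvals <- (1 + counts[[j]]) / (n_sim + 1)
  if (single) specs[[1]] else specs
}

#' Per-day circadian calls from a wavelet spectrum
#'
#' For each day of the record, takes the median of the pointwise surrogate
#' p-values over the day's 24 time points and all period-grid rows inside
#' the circadian band (default 23.5--24.5 h), and calls the day circadian if
#' this median is below `alpha`. Days containing any zero-filled point are
#' non-evaluable: no call is made where data was invented. Days whose band
#' pixels touch the cone of influence are called but flagged.
#'
#' @param spectrum a `wavelet_spectrum` with `pvals` computed.
#' @param band circadian period band in hours.
#' @param alpha significance level for the median p-value.
#' @param day_index optional day labels (default `1:n_days`).
#' @return data.frame of class `circadian_calls`: `day`, `median_p`,
#'   `is_circadian`, `evaluable`, `coi_clean`.
#' @export
call_circadian_days <- function(spectrum, band = c(23.5, 24.5), alpha = 0.05,
                                day_index = NULL) {
  stopifnot(inherits(spectrum, "wavelet_spectrum"))
  if (is.null(spectrum$pvals))
    stop("run surrogate_pvalues() before calling circadian days")
  rows <- which(spectrum$periods_h >= band[1] & spectrum$periods_h <= band[2])
  if (!length(rows)) stop("no period grid row inside the circadian band")
  n_days <- spectrum$n_time %/% 24L
  if (is.null(day_index)) day_index <- seq_len(n_days)
  out <- data.frame(day = day_index[seq_len(n_days)],
                    median_p = NA_real_, is_circadian = NA,
                    evaluable = FALSE, coi_clean = FALSE)
  for (d in seq_len(n_days)) {
    idx <- ((d - 1L) * 24L + 1L):(d * 24L)
    out$evaluable[d] <- !any(spectrum$fill_mask[idx])
    out$median_p[d] <- stats::median(spectrum$pvals[rows, idx])
    out$coi_clean[d] <- all(spectrum$coi_ok[rows, idx])
    if (out$evaluable[d]) out$is_circadian[d] <- out$median_p[d] < alpha
  }
  class(out) <- c("circadian_calls", class(out))
  out
}

#' Rhythm-proportion summaries per month or per period
#'
#' Divides the number of circadian days by the number of evaluable days per
#' animal per group. With `grouping = "month"` days are grouped into
#' consecutive 28-day months of the fattening phase; with
#' `grouping = "period"` into the supplied 14-day period definitions, where
#' a value is only reported when at least `min_days` evaluable days are
#' available in the period.
#'
#' @param calls a `circadian_calls` data.frame (or a named list of them, one
#'   per pig, which returns one combined table with a `pig_id` column).
#' @param grouping `"month"` or `"period"`.
#' @param periods period definitions from [assign_periods()] (required for
#'   `grouping = "period"`).
#' @param min_days minimum evaluable days for a per-period proportion.
#' @param month_len days per month of the phase.
#' @return data.frame with `group`, `n_evaluable_days`, `n_circadian_days`,
#'   `proportion_circadian` (`NA` when suppressed).
#' @export
summarise_rhythm <- function(calls, grouping = c("month", "period"),
                             periods = NULL, min_days = 7L, month_len = 28L) {
  grouping <- match.arg(grouping)
  if (!inherits(calls, "circadian_calls") && is.list(calls)) {
    out <- lapply(names(calls), function(id) {
      s <- summarise_rhythm(calls[[id]], grouping, periods, min_days, month_len)
      cbind(pig_id = id, s)
    })
    return(do.call(rbind, out))
  }
  grp <- if (grouping == "month") {
    (calls$day - min(calls$day)) %/% month_len + 1L
  } else {
    if (is.null(periods)) stop("'periods' required for per-period grouping")
    match_period(calls$day, periods)
  }
  keep <- !is.na(grp)
  agg <- stats::aggregate(
    cbind(evaluable = calls$evaluable[keep],
          circadian = calls$evaluable[keep] & calls$is_circadian[keep] %in% TRUE),
    by = list(group = grp[keep]), FUN = sum)
  prop <- ifelse(agg$evaluable > 0, agg$circadian / agg$evaluable, NA_real_)
  if (grouping == "period") prop[agg$evaluable < min_days] <- NA_real_
  data.frame(group = agg$group, n_evaluable_days = agg$evaluable,
             n_circadian_days = agg$circadian, proportion_circadian = prop)
}
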