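#' De-trended hourly series
#'
#' Container for the wavelet-ready form of an hourly intake series: the flat
#' time vector after LOESS de-trending (and, later, amplitude correction and
#' zero-filling), plus the LOESS fit kept for diagnostics and a mask of
#' points that were missing and zero-filled.
#'
#' @keywords internal
new_detrended <- function(values, fill_mask, trend_fit, pig_id = NA,
                          block_valid = NULL) {
  structure(list(values = values, fill_mask = fill_mask,
                 trend_fit = trend_fit, pig_id = pig_id,
                 block_valid = block_valid),
            class = "detrended_series")
}

#' @export
print.detrended_series <- function(x, ...) {
  cat(sprintf("<detrended_series> pig %s: %d points, %d filled/missing\n",
              x$pig_id, length(x$values), sum(x$fill_mask)))
  invisible(x)
}

#' LOESS de-trending of an hourly intake series
#'
#' Fits a locally weighted regression of hourly intake on the time index
#' over the non-missing points (`stats::loess`, tricube weights, `span`
#' fraction of points, default degree 2) and returns observed minus fit.
#' Missing points remain missing at this stage; the fit runs on the true
#' time index so gaps are respected. This removes the growth-driven rise in
#' average intake across the phase so the series has an approximately
#' constant mean.
#'
#' @param series an [hourly_series()] or a numeric vector (`NA` = missing).
#' @param span LOESS span in `(0, 1]`, fraction of points in each local fit.
#' @param degree local polynomial degree (1 or 2).
#' @return a `detrended_series` (values still `NA` at missing points).
#' @export
loess_detrend <- function(series, span = 0.75, degree = 2) {
  if (inherits(series, "hourly_series")) {
    y <- flatten_hours(series); pid <- series$pig_id
  } else { y <- as.numeric(series); pid <- NA }
  if (span <= 0 || span > 1) stop("'span' must lie in (0, 1]")
  ok <- !is.na(y)
  if (sum(ok) < 2L) stop("need at least 2 non-missing points to de-trend")
  t <- seq_along(y)
  fit <- stats::loess(y ~ t, span = span, degree = degree,
                      na.action = stats::na.exclude)
  trend <- stats::predict(fit, newdata = data.frame(t = t))
  new_detrended(y - trend, fill_mask = !ok, trend_fit = trend, pig_id = pid)
}

#' Seven-day amplitude correction
#'
#' Partitions the time axis into consecutive non-overlapping blocks of
#' `window_days` days (the final block may be shorter), computes the range
#' (max minus min) of the non-missing de-trended values in each block, and
#' divides every value in the block by that range. After correction each
#' valid block has in-block range exactly 1, stabilising the variance for
#' wavelet significance testing. Blocks whose range is below `min_range`
#' (e.g. near-empty weeks) pass through unscaled and are flagged invalid.
#'
#' @param detr a `detrended_series` from [loess_detrend()].
#' @param window_days block length in days (default 7).
#' @param min_range minimum range for a block to be scaled.
#' @return a `detrended_series` with `block_valid` (logical per block).
#' @export
amplitude_correct <- function(detr, window_days = 7, min_range = 1e-9) {
  stopifnot(inherits(detr, "detrended_series"))
  if (window_days < 1) stop("'window_days' must be >= 1")
  n <- length(detr$values)
  bl <- window_days * 24L
  n_blocks <- ceiling(n / bl)
  valid <- logical(n_blocks)
  v <- detr$values
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * bl + 1L):min(b * bl, n)
    xs <- v[idx][!detr$fill_mask[idx]]
    rg <- if (length(xs)) diff(range(xs)) else 0
    if (is.finite(rg) && rg >= min_range) {
      v[idx] <- v[idx] / rg
      valid[b] <- TRUE
    }
  }
  detr$values <- v
  detr$block_valid <- valid
  detr
}

#' Zero-fill missing points
#'
#' Replaces every missing point with zero so the wavelet transform can run
#' on a complete series. `fill_mask` records the replaced points; downstream
#' circadian calls treat days containing filled points as non-evaluable, so
#' the spectrum is only interpreted where no data was invented.
#'
#' @param detr a `detrended_series`.
#' @return the series with `NA` replaced by 0 (mask unchanged).
#' @export
zero_fill <- function(detr) {
  stopifnot(inherits(detr, "detrended_series"))
  detr$values[detr$fill_mask] <- 0
  detr
}

#' Full wavelet pre-processing pipeline
#'
#' Convenience composition: LOESS de-trend, amplitude-correct in
#' `window_days` blocks, zero-fill.
#'
#' @inheritParams loess_detrend
#' @inheritParams amplitude_correct
#' @return a wavelet-ready `detrended_series`.
#' @export
prepare_series <- function(series, span = 0.75, degree = 2, window_days = 7,
                           min_range = 1e-9) {
  zero_fill(amplitude_correct(loess_detrend(series, span, degree),
                              window_days, min_range))
}
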