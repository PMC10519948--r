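#' Per-animal hourly intake series
#'
#' The central container of the pipeline: one animal's hourly feed intake
#' (grams) over the study window, stored as a `day x 24` matrix with an
#' explicit missingness mask. Hour bin `h` (0--23) covers the half-open
#' interval `[h, h + 1)` hours post-midnight; this convention is shared by
#' every module.
#'
#' @param values numeric matrix, `n_days x 24`, intake in g; `NA` where
#'   missing.
#' @param pig_id,pen_id identifiers.
#' @param day_index integer vector of day numbers since arrival (length
#'   `nrow(values)`); defaults to `1:nrow(values)`.
#' @param missing_mask logical matrix congruent with `values`; defaults to
#'   `is.na(values)`.
#'
#' @return An object of class `hourly_series`.
#' @export
hourly_series <- function(values, pig_id, pen_id = NA,
                          day_index = seq_len(nrow(values)),
                          missing_mask = is.na(values)) {
  values <- as.matrix(values)
  if (ncol(values) != 24L)
    stop("'values' must have exactly 24 columns (hour bins 0-23)")
  if (!all(dim(missing_mask) == dim(values)))
    stop("'missing_mask' must be congruent with 'values'")
  if (length(day_index) != nrow(values))
    stop("'day_index' length must equal the number of days")
  if (any(values[!missing_mask] < 0, na.rm = TRUE))
    stop("non-missing intake values must be >= 0")
  values[missing_mask] <- NA_real_
  structure(
    list(pig_id = pig_id, pen_id = pen_id,
         values = values, missing_mask = missing_mask,
         day_index = as.integer(day_index)),
    class = "hourly_series")
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf("<hourly_series> pig %s (pen %s): %d days, %d missing\n",
              x$pig_id, x$pen_id, nrow(x$values), sum(rowAll_na(x))))
  invisible(x)
}

# days that are entirely missing
rowAll_na <- function(x) apply(x$missing_mask, 1L, all)

#' Flatten an hourly series to one vector
#'
#' Row-major flattening (day 1 hours 0--23, day 2 hours 0--23, ...), the time
#' ordering used by the de-trending and wavelet stages.
#'
#' @param series an [hourly_series()].
#' @return numeric vector of length `n_days * 24` with `NA` at missing hours.
#' @export
flatten_hours <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  as.vector(t(series$values))
}

#' Rebuild hourly series from the tidy long format
#'
#' Inverse of [hourly_long()] applied across animals: takes a data.frame
#' with columns `pig_id`, `pen_id`, `day`, `hour`, `intake_g`, `missing`
#' and returns the named list of [hourly_series()] objects.
#'
#' @param df long-format data.frame.
#' @return named list of [hourly_series()].
#' @export
hourly_from_long <- function(df) {
  out <- lapply(split(df, df$pig_id), function(d) {
    days <- sort(unique(d$day))
    vals <- matrix(NA_real_, length(days), 24)
    mm <- matrix(TRUE, length(days), 24)
    i <- match(d$day, days); j <- d$hour + 1L
    vals[cbind(i, j)] <- ifelse(d$missing, NA_real_, d$intake_g)
    mm[cbind(i, j)] <- d$missing
    hourly_series(vals, pig_id = d$pig_id[1], pen_id = d$pen_id[1],
                  day_index = days, missing_mask = mm)
  })
  out[order(names(out))]
}

#' Tidy long-format view of an hourly series
#'
#' @param series an [hourly_series()].
#' @return data.frame with columns `pig_id`, `pen_id`, `day`, `hour`,
#'   `intake_g`, `missing`.
#' @export
hourly_long <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  n <- nrow(series$values)
  data.frame(
    pig_id = series$pig_id, pen_id = series$pen_id,
    day = rep(series$day_index, each = 24L),
    hour = rep(0:23, n),
    intake_g = flatten_hours(series),
    missing = as.vector(t(series$missing_mask)))
}
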