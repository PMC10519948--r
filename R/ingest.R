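#' Visit-cleaning rule set
#'
#' Parameterised reconstruction of the EFS visit-cleaning rule families used
#' for electronic-feeder data: negative intakes, implausibly fast feeding
#' rates, implausibly long (or zero-duration, non-zero-intake) visits,
#' overlapping visits of the same animal, and whole pig-days on which too
#' large a fraction of visits was removed. All thresholds are configurable;
#' a rule is disabled by setting its threshold to `NA`.
#'
#' @param tol intake tolerance in g: rule 1 removes visits with
#'   `intake_g < -tol`; also the "non-zero intake" cut-off of rule 3.
#' @param rate_max maximum plausible feeding rate in g/min (rule 2).
#' @param dur_max maximum plausible visit duration in seconds (rule 3).
#' @param day_frac_max if more than this fraction of a pig-day's visits was
#'   removed by rules 1--4, all visits of that pig-day are removed (rule 5).
#'   `NA` disables.
#' @param overlap logical; enable removal of same-pig overlapping visits
#'   (rule 4).
#' @return object of class `cleaning_rules`.
#' @export
cleaning_rules <- function(tol = 0, rate_max = 150, dur_max = 3600,
                           day_frac_max = 0.25, overlap = TRUE) {
  structure(list(tol = tol, rate_max = rate_max, dur_max = dur_max,
                 day_frac_max = day_frac_max, overlap = overlap),
            class = "cleaning_rules")
}

visit_day <- function(ts, start_date) {
  as.integer(floor(as.numeric(difftime(ts, start_date, units = "days")))) + 1L
}

#' Clean feeder-visit records
#'
#' Applies the enabled rules of a [cleaning_rules()] set in order r1--r5.
#' Each visit is counted under the first rule it violates, so the per-rule
#' removal counts partition the removed set. Rule 5 then removes *all*
#' remaining visits of any pig-day whose removed-visit fraction (count basis,
#' rules 1--4) exceeds `day_frac_max`; those pig-days are reported so that
#' aggregation can mark them missing rather than zero. Records whose
#' timestamps cannot be interpreted (`NA` after parsing) are quarantined and
#' counted, not silently dropped.
#'
#' @param visits data.frame with `pig_id`, `pen_id`, `entry_ts`, `exit_ts`
#'   (POSIXct), `intake_g`.
#' @param rules a [cleaning_rules()].
#' @param start_date POSIXct origin of day 1, used to identify pig-days.
#' @return list with `visits` (surviving records), `report` (class
#'   `cleaning_report`: counts per rule, pig-days removed, fraction of intake
#'   removed), `removed_pig_days` (data.frame `pig_id`, `day`) and
#'   `quarantined` (unparseable records).
#' @export
clean_visits <- function(visits, rules = cleaning_rules(),
                         start_date = as.POSIXct("2020-12-15", tz = "UTC")) {
  stopifnot(inherits(rules, "cleaning_rules"))
  n_in <- nrow(visits)
  bad_ts <- is.na(visits$entry_ts) | is.na(visits$exit_ts) |
    visits$exit_ts < visits$entry_ts
  quarantined <- visits[bad_ts, , drop = FALSE]
  v <- visits[!bad_ts, , drop = FALSE]
  dur_s <- as.numeric(difftime(v$exit_ts, v$entry_ts, units = "secs"))
  rate <- ifelse(dur_s > 0, v$intake_g / (dur_s / 60), Inf)

  r1 <- if (!is.na(rules$tol)) v$intake_g < -rules$tol else rep(FALSE, nrow(v))
  r2 <- if (!is.na(rules$rate_max))
    !r1 & v$intake_g > rules$tol & rate > rules$rate_max else rep(FALSE, nrow(v))
  r3 <- if (!is.na(rules$dur_max))
    !r1 & !r2 & (dur_s > rules$dur_max |
                   (dur_s == 0 & v$intake_g > rules$tol))
  else rep(FALSE, nrow(v))
  # r4 runs on the survivors of r1-r3: a visit only counts as overlapping
  # when its predecessor is itself retained
  r4 <- rep(FALSE, nrow(v))
  if (isTRUE(rules$overlap) && nrow(v) > 1) {
    surv <- which(!(r1 | r2 | r3))
    if (length(surv) > 1) {
      ord <- surv[order(v$pig_id[surv], v$entry_ts[surv])]
      prev_exit <- c(as.POSIXct(NA), v$exit_ts[ord][-length(ord)])
      same_pig <- c(FALSE, v$pig_id[ord][-1] == v$pig_id[ord][-length(ord)])
      r4[ord] <- same_pig & !is.na(prev_exit) & v$entry_ts[ord] < prev_exit
    }
  }
  removed14 <- r1 | r2 | r3 | r4

  day <- visit_day(v$entry_ts, start_date)
  key <- paste(v$pig_id, day, sep = "\r")
  r5 <- rep(FALSE, nrow(v))
  removed_pig_days <- data.frame(pig_id = character(), day = integer())
  if (!is.na(rules$day_frac_max)) {
    frac <- tapply(removed14, key, mean)
    bad_days <- names(frac)[frac > rules$day_frac_max]
    r5 <- key %in% bad_days & !removed14
    if (length(bad_days)) {
      parts <- strsplit(bad_days, "\r", fixed = TRUE)
      removed_pig_days <- data.frame(
        pig_id = vapply(parts, `[`, "", 1L),
        day = as.integer(vapply(parts, `[`, "", 2L)))
    }
  }
  keep <- !(removed14 | r5)
  total_in <- sum(abs(visits$intake_g))
  report <- structure(list(
    n_visits_in = n_in,
    n_removed = c(neg_intake = sum(r1), rate = sum(r2), duration = sum(r3),
                  overlap = sum(r4), pig_day = sum(r5)),
    n_quarantined = nrow(quarantined),
    n_pig_days_removed = nrow(removed_pig_days),
    fraction_intake_removed =
      if (total_in > 0) 1 - sum(abs(v$intake_g[keep])) / total_in else 0),
    class = "cleaning_report")
  list(visits = v[keep, , drop = FALSE], report = report,
       removed_pig_days = removed_pig_days, quarantined = quarantined)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d visits in, %d removed (%.2f%% of intake)\n",
              x$n_visits_in, sum(x$n_removed),
              100 * x$fraction_intake_removed))
  print(x$n_removed)
  invisible(x)
}

#' Aggregate cleaned visits to per-animal hourly intake
#'
#' Sums visit intakes into calendar-hour bins per pig. A visit spanning an
#' hour boundary contributes to each bin proportionally to the time spent in
#' it (unbiased hourly mass assignment). Hours of pig-days removed during
#' cleaning are marked missing; hours without visits on retained days are 0.
#'
#' @param visits cleaned visit data.frame.
#' @param n_days number of study days (columns of the output matrices).
#' @param start_date POSIXct origin of day 1.
#' @param removed_pig_days data.frame `pig_id`, `day` of pig-days to mark
#'   missing (from [clean_visits()]).
#' @param pigs optional data.frame `pig_id`, `pen_id` forcing the output set
#'   of animals (pigs without surviving visits get all-zero series).
#' @return named list of [hourly_series()], one per pig.
#' @export
aggregate_hourly <- function(visits, n_days,
                             start_date = as.POSIXct("2020-12-15", tz = "UTC"),
                             removed_pig_days = NULL, pigs = NULL) {
  if (is.null(pigs)) {
    pigs <- unique(visits[, c("pig_id", "pen_id")])
    pigs <- pigs[order(pigs$pig_id), , drop = FALSE]
  }
  t0 <- as.numeric(start_date)
  # split visits at hour boundaries, proportional mass
  e <- as.numeric(visits$entry_ts) - t0
  x <- as.numeric(visits$exit_ts) - t0
  out <- vector("list", nrow(pigs))
  names(out) <- pigs$pig_id
  for (i in seq_len(nrow(pigs))) {
    idx <- which(visits$pig_id == pigs$pig_id[i])
    # collect (bin, amount) contributions, then accumulate in one pass with
    # extended-precision summation so aggregation is an exact inverse of the
    # synthetic visit split
    bins <- integer(0); amts <- numeric(0)
    for (j in idx) {
      lo <- e[j]; hi <- x[j]; w <- visits$intake_g[j]
      b1 <- floor(lo / 3600)
      b2 <- if (hi > lo) floor((hi - 1e-9) / 3600) else b1
      if (b2 <= b1) { # within one hour (or zero duration): no split
        bins <- c(bins, b1); amts <- c(amts, w)
      } else {
        for (b in b1:b2) {
          ov <- min(hi, (b + 1) * 3600) - max(lo, b * 3600)
          bins <- c(bins, b); amts <- c(amts, w * ov / (hi - lo))
        }
      }
    }
    vals <- matrix(0, n_days, 24)
    if (length(bins)) {
      keep_b <- bins %/% 24 + 1 >= 1 & bins %/% 24 + 1 <= n_days
      agg <- rowsum(amts[keep_b], bins[keep_b])
      b <- as.integer(rownames(agg))
      vals[cbind(b %/% 24 + 1, b %% 24 + 1)] <- agg[, 1]
    }
    mm <- matrix(FALSE, n_days, 24)
    if (!is.null(removed_pig_days)) {
      dd <- removed_pig_days$day[removed_pig_days$pig_id == pigs$pig_id[i]]
      dd <- dd[dd >= 1 & dd <= n_days]
      mm[dd, ] <- TRUE
      vals[dd, ] <- NA_real_
    }
    out[[i]] <- hourly_series(vals, pig_id = pigs$pig_id[i],
                              pen_id = pigs$pen_id[i], missing_mask = mm)
  }
  out
}

#' Read visit and welfare-event tables from CSV
#'
#' `read_visits_csv` expects columns `pig_id`, `pen_id`, `entry_ts`,
#' `exit_ts` (ISO-8601), `intake_g`; `read_events_csv` expects `pig_id`
#' (empty or `*` for cohort-level rows), `event_type` and `day`.
#'
#' @param path file path.
#' @param tz timestamp time zone.
#' @return a data.frame in the layout the cleaning/aggregation functions use.
#' @export
read_visits_csv <- function(path, tz = "UTC") {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pig_id", "pen_id", "entry_ts", "exit_ts", "intake_g")
  if (!all(need %in% names(v)))
    stop("visit CSV must contain columns: ", paste(need, collapse = ", "))
  v$entry_ts <- as.POSIXct(v$entry_ts, tz = tz,
                           tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                          "%Y-%m-%d %H:%M:%OS"))
  v$exit_ts <- as.POSIXct(v$exit_ts, tz = tz,
                          tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                         "%Y-%m-%d %H:%M:%OS"))
  v
}

#' @rdname read_visits_csv
#' @export
read_events_csv <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pig_id", "event_type", "day")
  if (!all(need %in% names(e)))
    stop("event CSV must contain columns: ", paste(need, collapse = ", "))
  e$pig_id[e$pig_id %in% c("", "*")] <- NA
  e$day <- as.integer(e$day)
  e
}

#' Remove pig-days expected to deviate from basal feeding
#'
#' Day-level welfare filtering: marks as missing (1) every day within +/- 3
#' days (inclusive) of a day with a high disease score for that pig, (2) all
#' days strictly before the first health observation, and (3) all days
#' strictly after the first slaughter departure of the cohort.
#'
#' @param series an [hourly_series()] or list thereof.
#' @param events data.frame with columns `pig_id` (or `NA`/`"*"` for
#'   cohort-level events), `event_type` in
#'   `{"disease", "first_obs", "slaughter"}` and `day` (study day index).
#' @param disease_window half-width in days of the disease exclusion window
#'   (inclusive at both ends).
#' @return same shape as `series`, with an attribute `"n_days_removed"` per
#'   series counting newly removed days.
#' @export
filter_pig_days <- function(series, events, disease_window = 3L) {
  if (!inherits(series, "hourly_series")) {
    known <- vapply(series, function(s) s$pig_id, "")
    extra <- setdiff(unique(events$pig_id[events$event_type == "disease"]), known)
    if (length(extra))
      warning("events reference pigs absent from the data: ",
              paste(extra, collapse = ", "))
    return(lapply(series, filter_pig_days, events = events,
                  disease_window = disease_window))
  }
  ev_pig <- events[is.na(events$pig_id) | events$pig_id %in% c("*", series$pig_id), ]
  drop <- rep(FALSE, nrow(series$values))
  days <- series$day_index
  for (d in ev_pig$day[ev_pig$event_type == "disease" &
                         !is.na(ev_pig$pig_id) &
                         ev_pig$pig_id == series$pig_id])
    drop <- drop | (days >= d - disease_window & days <= d + disease_window)
  fo <- ev_pig$day[ev_pig$event_type == "first_obs"]
  if (length(fo)) drop <- drop | days < max(fo[is.finite(fo)])
  sl <- ev_pig$day[ev_pig$event_type == "slaughter"]
  if (length(sl)) drop <- drop | days > min(sl[is.finite(sl)])
  newly <- drop & !apply(series$missing_mask, 1L, all)
  series$values[drop, ] <- NA_real_
  series$missing_mask[drop, ] <- TRUE
  attr(series, "n_days_removed") <- sum(newly)
  series
}
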