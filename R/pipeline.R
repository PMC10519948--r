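#' Run the full analysis pipeline on a cohort of hourly series
#'
#' Orchestrates the per-animal stages end-to-end: wavelet pre-processing
#' and circadian detection (shared surrogate ensemble across animals of
#' equal record length), hurdle-GAM fitting with likelihood-ratio model
#' comparisons, feature extraction, and the cohort-level consistency
#' statistics. Intended for scripted analyses; each stage is equally
#' callable on its own.
#'
#' @param hourly list of [hourly_series()] (e.g. from [simulate_cohort()] or
#'   [aggregate_hourly()]).
#' @param period_len modelling-period length in days.
#' @param n_sim surrogate count for wavelet significance.
#' @param seed seed for the surrogate ensemble.
#' @param alpha significance level for circadian calls and LR summaries.
#' @param min_days per-period availability threshold.
#' @param run_wavelet,run_lr stage toggles.
#' @param transforms normalising transforms for the period models; `NULL`
#'   skips the mixed-model stage.
#' @return list with `calls`, `rhythm` (per-period and per-month),
#'   `fits`, `lr` (per-pig LR results), `features` (joined table),
#'   `period_models`, `icc`, `period_tests`, `spearman` (per period).
#' @export
run_pipeline <- function(hourly, period_len = 14L, n_sim = 1000, seed = 1L,
                         alpha = 0.05, min_days = 7L,
                         run_wavelet = TRUE, run_lr = TRUE,
                         transforms = default_transforms()) {
  stopifnot(length(hourly) >= 1)
  ids <- vapply(hourly, function(s) as.character(s$pig_id), "")
  names(hourly) <- ids
  day_range <- range(unlist(lapply(hourly, function(s) s$day_index)))
  periods <- assign_periods(day_range, period_len)

  calls <- NULL; rhythm_period <- NULL; rhythm_month <- NULL
  if (run_wavelet) {
    specs <- lapply(hourly, function(s) morlet_cwt(prepare_series(s)))
    specs <- surrogate_pvalues(specs, n_sim = n_sim, seed = seed)
    calls <- lapply(seq_along(specs), function(i)
      call_circadian_days(specs[[i]], alpha = alpha,
                          day_index = hourly[[i]]$day_index))
    names(calls) <- ids
    rhythm_period <- summarise_rhythm(calls, "period", periods = periods,
                                      min_days = min_days)
    rhythm_month <- summarise_rhythm(calls, "month")
  }

  fits <- list(); lr <- NULL; features <- NULL
  for (id in ids) {
    s <- hourly[[id]]
    pa <- period_availability(s, periods, min_days)
    if (!any(pa$retained)) next
    fit <- try(fit_hurdle(s, pa), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("hurdle fit failed for pig ", id, ": ",
              attr(fit, "condition")$message)
      next
    }
    fits[[id]] <- fit
    if (run_lr) {
      red_t <- fit_hurdle(s, pa, diurnal = "none")
      red_s <- fit_hurdle(s, pa, diurnal = "single")
      lr <- rbind(lr, cbind(pig_id = id, reduced = "trend_only",
                            lr_compare(fit, red_t)),
                  cbind(pig_id = id, reduced = "single_diurnal",
                        lr_compare(fit, red_s)))
    }
    features <- rbind(features, diurnal_features(fit))
  }
  if (!is.null(features) && !is.null(rhythm_period))
    features <- join_circadian(features, rhythm_period)

  period_models <- list(); icc <- NULL; period_tests <- list(); spearman <- list()
  if (!is.null(transforms) && !is.null(features)) {
    tc <- transform_and_check(features, transforms)
    for (nm in names(transforms)) {
      if (!nm %in% names(features)) next
      d <- data.frame(value = tc$features[[nm]],
                      period_id = features$period_id,
                      pen_id = features$pen_id, pig_id = features$pig_id)
      pm <- try(fit_period_model(d), silent = TRUE)
      if (inherits(pm, "try-error")) next
      period_models[[nm]] <- pm
      icc <- rbind(icc, cbind(feature = nm, compute_icc(pm)))
      period_tests[[nm]] <- try(test_period_effect(pm), silent = TRUE)
    }
    for (p in unique(features$period_id)) {
      sm <- try(spearman_matrix(features, period = p), silent = TRUE)
      if (!inherits(sm, "try-error")) spearman[[as.character(p)]] <- sm
    }
  }
  lr_summary <- NULL
  if (!is.null(lr))
    lr_summary <- stats::aggregate(list(pct_rejected = lr$p < alpha),
                                   by = list(reduced = lr$reduced),
                                   FUN = function(z) 100 * mean(z))
  list(periods = periods, calls = calls,
       rhythm = list(period = rhythm_period, month = rhythm_month),
       fits = fits, lr = lr, lr_summary = lr_summary, features = features,
       period_models = period_models, icc = icc,
       period_tests = period_tests, spearman = spearman)
}
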