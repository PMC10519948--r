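#' Strength label for correlations and ICCs
#'
#' Weak below 0.4 in absolute value, moderate in `[0.4, 0.6)`, strong at 0.6
#' and above.
#'
#' @param x numeric vector of coefficients.
#' @return character vector of labels (`NA` propagates).
#' @export
strength_label <- function(x) {
  out <- rep(NA_character_, length(x))
  a <- abs(x)
  out[a < 0.4] <- "weak"
  out[a >= 0.4 & a < 0.6] <- "moderate"
  out[a >= 0.6] <- "strong"
  out
}

#' Per-feature normalising transforms
#'
#' The transform dialect used before the period mixed models: square root
#' for the lowest intake and the lowest eating probability, logarithm for
#' the height and width of the highest peak, and a fixed constant minus the
#' square root for the peak timing (default constant 24, the hour-scale
#' maximum; configurable since the choice is a convention). Everything else
#' stays on its identity scale.
#'
#' @param peak_time_const the constant of the `const - sqrt(x)` timing
#'   transform.
#' @return named list mapping feature name to a transform spec
#'   `list(type, const)`.
#' @export
default_transforms <- function(peak_time_const = 24) {
  list(peak_time_h = list(type = "const_minus_sqrt", const = peak_time_const),
       peak_height = list(type = "log"),
       peak_width = list(type = "log"),
       lowest_intake = list(type = "sqrt"),
       night_prop = list(type = "identity"),
       min_prob_eat = list(type = "sqrt"),
       max_prob_eat = list(type = "identity"),
       prop_circadian_days = list(type = "identity"))
}

apply_transform <- function(x, spec) {
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE))
      stop(sprintf("%s transform undefined for rows: %s", what,
                   paste(utils::head(which(cond), 10), collapse = ", ")))
  }
  switch(spec$type,
         identity = x,
         sqrt = { bad(x < 0, "sqrt"); sqrt(x) },
         log = { bad(x <= 0, "log"); log(x) },
         const_minus_sqrt = { bad(x < 0, "const_minus_sqrt")
           spec$const - sqrt(x) },
         stop("unknown transform type: ", spec$type))
}

#' Transform features and gate on residual normality
#'
#' Applies the per-feature transforms, then computes the Shapiro--Wilk W on
#' the residuals of a per-feature fixed-effect fit (`value ~ period`),
#' flagging features whose W falls below the threshold (default 0.9). The
#' same check can be re-run on mixed-model residuals once those are fitted.
#'
#' @param features long-ish feature table with `period_id` and feature
#'   columns.
#' @param transforms named list as from [default_transforms()]; features
#'   without an entry pass through unchanged.
#' @param shapiro_threshold minimum acceptable W.
#' @return list with `features` (transformed) and `normality` (data.frame
#'   `feature`, `W`, `ok`).
#' @export
transform_and_check <- function(features, transforms = default_transforms(),
                                shapiro_threshold = 0.9) {
  out <- features
  norm <- data.frame(feature = character(), W = numeric(), ok = logical())
  for (nm in names(transforms)) {
    if (!nm %in% names(out)) next
    out[[nm]] <- apply_transform(out[[nm]], transforms[[nm]])
    x <- out[[nm]]; keep <- is.finite(x)
    W <- NA_real_
    if (sum(keep) >= 10 && stats::var(x[keep]) > 0) {
      res <- stats::resid(stats::lm(x ~ factor(features$period_id),
                                    subset = keep))
      # shapiro.test caps at 5000 observations
      if (length(res) > 5000) res <- sample(res, 5000)
      W <- unname(stats::shapiro.test(res)$statistic)
    }
    norm <- rbind(norm, data.frame(feature = nm, W = W,
                                   ok = is.na(W) | W >= shapiro_threshold))
  }
  list(features = out, normality = norm)
}

#' Period mixed model with AR(1) residuals for one feature
#'
#' `value ~ period + (1 | pen) + (1 | pig)` with the residual structure an
#' AR(1) process across consecutive periods within pig (fitted as an ar1
#' random effect while the independent residual variance is suppressed, so
#' the AR(1) diagonal *is* the residual variance). Pigs missing interior
#' periods keep true time gaps: the AR correlation between their retained
#' periods decays as `rho^gap`.
#'
#' @param data data.frame with columns `value`, `period_id`, `pen_id`,
#'   `pig_id` (one row per pig-period).
#' @return object of class `period_model`: the glmmTMB fit plus extracted
#'   variance components `var_pig`, `var_pen`, `var_resid` (AR(1) diagonal),
#'   `ar1_rho`, and a `singular` flag.
#' @export
fit_period_model <- function(data) {
  need <- c("value", "period_id", "pen_id", "pig_id")
  if (!all(need %in% names(data)))
    stop("data must contain: ", paste(need, collapse = ", "))
  data <- data[is.finite(data$value), , drop = FALSE]
  if (length(unique(data$period_id)) < 2) stop("need >= 2 periods")
  if (length(unique(data$pen_id)) < 2) stop("need >= 2 pens")
  d <- data.frame(value = data$value,
                  period = factor(data$period_id,
                                  levels = sort(unique(data$period_id))),
                  pen = factor(data$pen_id), pig = factor(data$pig_id))
  conv_warnings <- character()
  m <- withCallingHandlers(
    glmmTMB::glmmTMB(
      # ar1() must appear unqualified for glmmTMB to recognise the
      # covariance structure
      stats::as.formula(
        "value ~ period + (1 | pen) + (1 | pig) + ar1(period + 0 | pig)"),
      dispformula = ~0, data = d,
      control = glmmTMB::glmmTMBControl(optimizer = stats::optim,
                                        optArgs = list(method = "BFGS"))),
    warning = function(w) {
      # boundary fits (a variance at ~0) commonly flag a non-PD Hessian;
      # record instead of failing, per the singular-fit contract
      conv_warnings <<- c(conv_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  vc <- glmmTMB::VarCorr(m)$cond
  var_pen <- unname(attr(vc$pen, "stddev"))^2
  var_pig <- unname(attr(vc$pig, "stddev"))^2
  ar_block <- vc$pig.1
  var_resid <- unname(attr(ar_block, "stddev"))[1]^2
  corr <- attr(ar_block, "correlation")
  ar1_rho <- if (nrow(corr) > 1) corr[1, 2] else NA_real_
  singular <- any(c(var_pen, var_pig, var_resid) < 1e-8) ||
    length(conv_warnings) > 0
  structure(list(model = m, data = d,
                 var_pig = var_pig, var_pen = var_pen, var_resid = var_resid,
                 ar1_rho = ar1_rho, singular = singular,
                 convergence_warnings = conv_warnings),
            class = "period_model")
}

#' @export
print.period_model <- function(x, ...) {
  cat(sprintf(paste0("<period_model> var_pig %.3f, var_pen %.3f, ",
                     "var_resid %.3f (AR1 rho %.2f)%s\n"),
              x$var_pig, x$var_pen, x$var_resid, x$ar1_rho,
              if (x$singular) " [boundary]" else ""))
  invisible(x)
}

#' Chi-squared test of the period effect with Tukey post-hoc contrasts
#'
#' Wald chi-squared test on the period fixed-effect block (a likelihood-
#' ratio variant is available via `type = "LR"`). If significant at
#' `alpha`, all pairwise period contrasts are computed with Tukey-style
#' multiplicity adjustment and summarised as a compact letter display.
#'
#' @param pm a [fit_period_model()] object.
#' @param type `"Wald"` or `"LR"`.
#' @param alpha significance level gating the post-hoc step.
#' @return object of class `period_effect`: `chi2`, `df`, `p`, and (when
#'   significant) `pairwise` (emmeans contrast table) and `letters`.
#' @export
test_period_effect <- function(pm, type = c("Wald", "LR"), alpha = 0.05) {
  type <- match.arg(type)
  stopifnot(inherits(pm, "period_model"))
  m <- pm$model
  if (type == "Wald") {
    b <- glmmTMB::fixef(m)$cond
    V <- stats::vcov(m)$cond
    idx <- grep("^period", names(b))
    chi2 <- drop(t(b[idx]) %*% solve(V[idx, idx]) %*% b[idx])
    df <- length(idx)
  } else {
    m0 <- stats::update(m, . ~ . - period)
    chi2 <- 2 * (as.numeric(stats::logLik(m)) - as.numeric(stats::logLik(m0)))
    df <- nlevels(pm$data$period) - 1
  }
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  pairwise <- NULL; letters <- NULL
  if (p < alpha) {
    emm <- emmeans::emmeans(m, "period")
    pairwise <- as.data.frame(emmeans::contrast(emm, "pairwise",
                                                adjust = "tukey"))
    means <- as.data.frame(emm)
    letters <- compact_letters(levels = as.character(means$period),
                               means = means$emmean,
                               contrasts = pairwise, alpha = alpha)
  }
  structure(list(chi2 = chi2, df = df, p = p,
                 pairwise = pairwise, letters = letters, type = type),
            class = "period_effect")
}

#' @export
print.period_effect <- function(x, ...) {
  cat(sprintf("<period_effect> %s chi2 = %.1f (df %d), p = %.3g\n",
              x$type, x$chi2, x$df, x$p))
  if (!is.null(x$letters)) {
    cat("  letters:", paste(names(x$letters), x$letters, sep = ":",
                            collapse = "  "), "\n")
  }
  invisible(x)
}

# compact letter display from Tukey-adjusted pairwise contrasts: levels are
# ordered by mean; every maximal run of mutually non-different levels gets
# one letter, and runs contained in another run are absorbed
compact_letters <- function(levels, means, contrasts, alpha = 0.05) {
  k <- length(levels)
  notdiff <- diag(TRUE, k)
  dimnames(notdiff) <- list(levels, levels)
  for (i in seq_len(nrow(contrasts))) {
    pair <- strsplit(contrasts$contrast[i], " - ", fixed = TRUE)[[1]]
    pair <- gsub("^period", "", trimws(pair))
    nd <- contrasts$p.value[i] >= alpha
    notdiff[pair[1], pair[2]] <- nd
    notdiff[pair[2], pair[1]] <- nd
  }
  ord <- order(means)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(notdiff[ord[i:(j + 1)], ord[i:(j + 1)]])) j <- j + 1
    runs[[length(runs) + 1]] <- ord[i:j]
  }
  keep <- !vapply(seq_along(runs), function(a)
    any(vapply(seq_along(runs), function(b)
      a != b && all(runs[[a]] %in% runs[[b]]), TRUE)), TRUE)
  runs <- unique(runs[keep])
  out <- stats::setNames(rep("", k), levels)
  for (r in seq_along(runs))
    out[runs[[r]]] <- paste0(out[runs[[r]]], letters[r])
  out[order(names(out))]
}

#' Pen and pig intraclass correlations
#'
#' `icc = var_component / (var_pig + var_pen + var_resid)`, the residual
#' term being the diagonal of the AR(1) covariance. Variance-ratio ICCs are
#' non-negative, so only the positive strength bands apply.
#'
#' @param pm a [fit_period_model()] object.
#' @return data.frame `component`, `variance`, `icc`, `label`.
#' @export
compute_icc <- function(pm) {
  stopifnot(inherits(pm, "period_model"))
  tot <- pm$var_pig + pm$var_pen + pm$var_resid
  if (tot <= 0) stop("all variance components are zero; ICC undefined")
  icc <- c(pig = pm$var_pig, pen = pm$var_pen, resid = pm$var_resid) / tot
  data.frame(component = names(icc),
             variance = c(pm$var_pig, pm$var_pen, pm$var_resid),
             icc = unname(icc),
             label = strength_label(unname(icc)))
}

#' Per-period Spearman correlation matrix over features
#'
#' Pairwise-complete Spearman rank correlations (average ranks on ties)
#' between all feature columns for one period, with strength labels.
#' Constant columns yield `NA` correlations and are flagged.
#'
#' @param features combined feature table (with `period_id`).
#' @param period period id to subset on; `NULL` uses all rows.
#' @param cols feature columns; defaults to the eight features plus
#'   `prop_circadian_days` where present.
#' @return object of class `spearman_matrix`: `rho` (symmetric, unit
#'   diagonal), `labels`, `n`, `constant_cols`.
#' @export
spearman_matrix <- function(features, period = NULL, cols = NULL) {
  if (!is.null(period)) features <- features[features$period_id %in% period, ]
  if (is.null(cols))
    cols <- intersect(c("n_peaks", "peak_time_h", "peak_height", "peak_width",
                        "lowest_intake", "night_prop", "min_prob_eat",
                        "max_prob_eat", "prop_circadian_days"),
                      names(features))
  x <- features[, cols, drop = FALSE]
  if (sum(stats::complete.cases(x)) < 3)
    stop("need at least 3 complete rows for a correlation matrix")
  const <- vapply(x, function(v) stats::var(v, na.rm = TRUE) == 0, TRUE)
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- 1
  labels <- matrix(strength_label(rho), nrow(rho), ncol(rho),
                   dimnames = dimnames(rho))
  structure(list(rho = rho, labels = labels, n = nrow(x),
                 constant_cols = names(const)[const]),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, ...) {
  cat(sprintf("<spearman_matrix> %d rows\n", x$n))
  print(round(x$rho, 2))
  invisible(x)
}
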