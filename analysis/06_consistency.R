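#!/usr/bin/env Rscript
# Stage 6 -- consistency statistics over the feature table.
#
# Features are transformed toward normality (sqrt / log / 24 - sqrt for the
# peak timing), checked with Shapiro-Wilk W >= 0.9 on residuals, and each
# is modelled with a linear mixed model: period fixed, pen and pig random,
# AR(1) residuals across consecutive periods within pig. The period effect
# is tested with a Wald chi-squared test (Tukey-adjusted pairwise contrasts
# and compact letters when significant), pen and pig intraclass
# correlations are computed from the variance components, and per-period
# Spearman matrices associate all features including the circadian-day
# proportion.

suppressMessages(library(circafeed))

features <- read.csv("results/features.csv")
tc <- transform_and_check(features)
print(tc$normality)

table1 <- NULL; icc_all <- NULL; letters_all <- list()
for (nm in names(default_transforms())) {
  if (!nm %in% names(features)) next
  d <- data.frame(value = tc$features[[nm]], period_id = features$period_id,
                  pen_id = features$pen_id, pig_id = features$pig_id)
  pm <- tryCatch(fit_period_model(d), error = function(e) NULL)
  if (is.null(pm)) next
  te <- test_period_effect(pm)
  icc <- compute_icc(pm)
  icc_all <- rbind(icc_all, cbind(feature = nm, icc))
  means <- aggregate(features[[nm]], list(period = features$period_id),
                     function(z) c(mean = mean(z, na.rm = TRUE),
                                   se = sd(z, na.rm = TRUE) /
                                     sqrt(sum(is.finite(z)))))
  table1 <- rbind(table1, data.frame(
    feature = nm, period = means$period,
    mean = means$x[, "mean"], se = means$x[, "se"],
    chi2 = te$chi2, p = te$p,
    letter = if (!is.null(te$letters))
      te$letters[as.character(means$period)] else "",
    icc_pen = icc$icc[icc$component == "pen"],
    icc_pig = icc$icc[icc$component == "pig"],
    singular_fit = pm$singular))
}
write.csv(table1, "results/period_effects.csv", row.names = FALSE)
write.csv(icc_all, "results/icc.csv", row.names = FALSE)

rho_long <- NULL
for (p in sort(unique(features$period_id))) {
  sm <- tryCatch(spearman_matrix(features, period = p),
                 error = function(e) NULL)
  if (is.null(sm)) next
  idx <- which(upper.tri(sm$rho), arr.ind = TRUE)
  rho_long <- rbind(rho_long, data.frame(
    period = p,
    feature_a = rownames(sm$rho)[idx[, 1]],
    feature_b = colnames(sm$rho)[idx[, 2]],
    rho = sm$rho[idx], label = sm$labels[idx], n = sm$n))
}
write.csv(rho_long, "results/spearman.csv", row.names = FALSE)

cat("\nperiod effects (Wald chi2 p-values):\n")
print(unique(table1[, c("feature", "chi2", "p")]), row.names = FALSE)
cat("\npig ICCs:\n")
print(unique(table1[, c("feature", "icc_pen", "icc_pig")]), row.names = FALSE)
strong <- rho_long[abs(rho_long$rho) >= 0.6 & rho_long$period == 1, ]
cat("\nstrong period-1 associations:\n")
print(strong[order(strong$rho), c("feature_a", "feature_b", "rho")],
      row.names = FALSE)
cat("\nwrote results/period_effects.csv, icc.csv, spearman.csv\n")
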