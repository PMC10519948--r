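#!/usr/bin/env Rscript
# Stage 5 -- extract the eight diurnal-pattern features per pig-period.
#
# From each retained pig-period's de-trended prediction curve: number of
# peaks, timing/height/width of the highest peak, lowest intake, proportion
# of intake at night (21:00-05:00), and the minimum and maximum probability
# of eating over the period's full hour x day surface (the two day-to-day
# consistency features). The per-period proportion of circadian days from
# stage 3 is joined on, completing the feature table that all consistency
# statistics run on. Fits are reproduced from the hourly table (they take
# seconds) so each stage exchanges only plain-text files.

suppressMessages(library(circafeed))

hourly <- hourly_from_long(read.csv("results/hourly_intake.csv"))
periods <- assign_periods(c(1, 83))
rhythm <- read.csv("results/rhythm_by_period.csv")

features <- NULL
for (id in names(hourly)) {
  s <- hourly[[id]]
  pa <- period_availability(s, periods)
  if (!any(pa$retained)) next
  features <- rbind(features, diurnal_features(fit_hurdle(s, pa)))
}
features <- join_circadian(features, rhythm)
write.csv(features, "results/features.csv", row.names = FALSE)

cat(sprintf("feature table: %d pig-periods from %d pigs\n",
            nrow(features), length(unique(features$pig_id))))
cat(sprintf("number of peaks: mean %.1f, range %d-%d\n",
            mean(features$n_peaks), min(features$n_peaks),
            max(features$n_peaks)))
cat(sprintf("night intake share: mean %.2f (night feeders present: %s)\n",
            mean(features$night_prop),
            ifelse(any(features$night_prop > 0.33), "yes", "no")))
cat("wrote results/features.csv\n")
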