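#!/usr/bin/env Rscript
# Stage 2 -- clean visit records, aggregate to hourly intake, filter
# welfare-affected pig-days.
#
# The cleaning rules target the classic EFS error signatures: negative
# intakes, implausible feeding rates (> 150 g/min), overlong or
# zero-duration visits, same-pig overlaps, and whole pig-days on which more
# than a quarter of visits had to be removed (aggregating the remainder of
# such days would bias hourly totals downward, so the day is dropped
# entirely and marked missing, not zero). Day-level welfare filters then
# remove +/- 3 days around disease scores, days before the first health
# observation, and days after the first slaughter departure.

suppressMessages(library(circafeed))

visits <- read_visits_csv("results/visits_raw.csv")
events <- read_events_csv("results/welfare_events.csv")
n_days <- 83

cl <- clean_visits(visits, cleaning_rules())
print(cl$report)

hourly <- aggregate_hourly(cl$visits, n_days = n_days,
                           removed_pig_days = cl$removed_pig_days)
hourly <- filter_pig_days(hourly, events)
removed <- vapply(hourly, function(s) attr(s, "n_days_removed"), 0)
cat(sprintf("welfare filters removed %d pig-days (%.1f%% of %d)\n",
            sum(removed), 100 * sum(removed) / (length(hourly) * n_days),
            length(hourly) * n_days))

long <- do.call(rbind, lapply(hourly, hourly_long))
write.csv(long, "results/hourly_intake.csv", row.names = FALSE)
jsonlite::write_json(unclass(cl$report), "results/cleaning_report.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/hourly_intake.csv, cleaning_report.json\n")
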