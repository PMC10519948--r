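#!/usr/bin/env Rscript
# Stage 1 -- simulate an EFS cohort with known ground truth.
#
# Emulates the study design the pipeline targets: pens of group-housed
# growing-finishing pigs, one electronic feeding station per pen, monitored
# over an 83-day phase during which daily intake ramps up with growth.
# Pigs are assigned a mix of diurnal profiles (alternans, single afternoon
# peak, night feeding, flat/irregular) at different day-to-day consistency
# levels, so every downstream claim can be checked against what was
# programmed. A small rate of recording errors is injected to exercise the
# cleaning stage, and welfare events (disease days, first health
# observation, slaughter departure) are drawn to exercise the day filters.
#
# Scaled to 4 pens x 6 pigs here so the full chain runs in minutes; the
# design itself (83 days, 11-pig pens) only changes the two constants below.

suppressMessages(library(circafeed))
dir.create("results", showWarnings = FALSE)
set.seed(20201215)

spec <- cohort_spec(n_pens = 4, pigs_per_pen = 6, n_days = 83,
                    missing_day_prob = 0.02, seed = 20201215)
profiles <- list(profile_alternans(consistency = 0.95),
                 profile_single_peak(consistency = 0.9),
                 profile_alternans(consistency = 0.8),
                 profile_night_feeder(consistency = 0.4),
                 profile_flat(consistency = 0.3),
                 profile_single_peak(consistency = 0.7))
co <- simulate_cohort(spec, profiles = profiles)

inj <- inject_errors(co$visits, error_spec(neg_intake_rate = 0.01,
                                           rate_spike_rate = 0.01,
                                           long_visit_rate = 0.005))

# welfare events: a disease bout for a handful of pigs, observations start
# on day 5, first slaughter departure on day 75
sick <- sample(co$pigs$pig_id, 4)
events <- rbind(
  data.frame(pig_id = sick, event_type = "disease",
             day = sample(20:60, length(sick))),
  data.frame(pig_id = NA, event_type = "first_obs", day = 5),
  data.frame(pig_id = NA, event_type = "slaughter", day = 75))

write_cohort(list(visits = inj$visits, hourly = co$hourly),
             "results/visits_raw.csv", "results/ground_truth.json")
write.csv(events, "results/welfare_events.csv", row.names = FALSE)
write.csv(cbind(co$pigs,
                consistency = vapply(co$hourly, function(s)
                  attr(s, "truth")$profile$consistency, 0)),
          "results/pig_truth.csv", row.names = FALSE)
cat(sprintf("simulated %d pigs, %d visits (%d corrupted), %d welfare events\n",
            nrow(co$pigs), nrow(inj$visits),
            sum(inj$labels$label == "corrupted"), nrow(events)))
cat("wrote results/visits_raw.csv, welfare_events.csv, ground_truth.json\n")
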