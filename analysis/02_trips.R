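#!/usr/bin/env Rscript
# Stage 2: segment fixes into foraging trips with the 2-km colony buffer,
# drop late-incubation trips, and extract the four trip metrics.
library(boldtrack)

seed <- as.integer(Sys.getenv("BOLDTRACK_SEED", "1"))
cfg <- sim_config(seed = seed)

fixes <- read_gps_csv("results/data/gps_fixes.csv")
trips <- segment_trips(fixes, cfg$colony)
trips <- assign_phase(trips, read.csv("results/data/trip_meta.csv"))
cat("Segmented", length(trips), "trips from", nrow(fixes), "fixes.\n")

brooding <- filter_phase(trips, "brooding")
cat(length(trips) - length(brooding),
    "trips excluded as late-incubation;", length(brooding), "retained.\n")
brooding <- Filter(function(tr) isTRUE(tr$complete), brooding)

metrics <- do.call(rbind, lapply(brooding, trip_metrics, colony = cfg$colony))
write.csv(metrics, "results/trip_metrics.csv", row.names = FALSE)
cat("Trip metrics written for", nrow(metrics), "complete brooding trips.\n")
cat(sprintf("Median foraging range %.0f km; median duration %.1f h.\n",
            median(metrics$max_range_km), median(metrics$duration_h)))
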