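#!/usr/bin/env Rscript
# Stage 4: classify ARS-zone habitat from bathymetry (shelf / shelf edge /
# oceanic) and compute fix-level overlap with 19-km, +1-h discarding zones.
library(boldtrack)

seed <- as.integer(Sys.getenv("BOLDTRACK_SEED", "1"))
cfg <- sim_config(seed = seed)

zones <- read.csv("results/ars_zones.csv")
grid <- read_bathymetry("results/data/bathymetry.asc")
zones$depth_m <- depth_at(grid, zones$centre_lat, zones$centre_lon)
zones$habitat <- classify_habitat(zones$depth_m)
write.csv(zones, "results/ars_zones_habitat.csv", row.names = FALSE)
cat("Habitat of ARS centres:\n")
print(table(zones$habitat))

ev <- read_fishing_csv("results/data/fishing_events.csv")
dz <- build_discarding_zones(ev)
fixes <- read_gps_csv("results/data/gps_fixes.csv")
trips <- assign_phase(segment_trips(fixes, cfg$colony),
                      read.csv("results/data/trip_meta.csv"))
brooding <- Filter(function(tr) isTRUE(tr$complete),
                   filter_phase(trips, "brooding"))
ov <- do.call(rbind, lapply(brooding, trip_overlap_summary, zones = dz))
write.csv(ov, "results/overlap_summary.csv", row.names = FALSE)

bird_any <- tapply(ov$any_overlap, ov$bird_id, any)
book <- overlap_bookkeeping(nrow(ov), sum(ov$any_overlap),
                            length(bird_any), sum(bird_any))
cat(sprintf("Fisheries overlap: %d of %d trips (%d%%), %d of %d birds (%d%%).\n",
            sum(ov$any_overlap), nrow(ov), book$pct_trips,
            sum(bird_any), length(bird_any), book$pct_birds))
at_v <- ov$prop_fixes[ov$any_overlap]
cat(sprintf("Mean share of trip time at vessels (overlapping trips): %.1f%%.\n",
            100 * mean(at_v)))
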