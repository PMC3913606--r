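#!/usr/bin/env Rscript
# Stage 5: PC1 personality scores (boldness from the assay counts, foraging
# personality from the trip metrics), repeatability of each, and the
# between-context correlation (behavioural syndrome).
library(boldtrack)

seed <- as.integer(Sys.getenv("BOLDTRACK_SEED", "1"))

beh <- read.csv("results/data/behaviour.csv")
bm <- beh[, c("peck_count", "lunge_count", "vocalise_count", "snap_count",
              "sitting_s")]
pca_b <- pca_correlation(bm, anchor = "peck_count")
cat(sprintf("Boldness PCA: PC1 explains %.0f%% of assay variance.\n",
            100 * pca_b$proportion[1]))
obs_score <- project_pc1(pca_b, bm)
boldness <- individual_boldness(obs_score, beh$bird_id, beh$obs_number,
                                as.Date(beh$date))
rb <- repeatability(fit_lmm_random_intercept(obs_score, group = beh$bird_id),
                    n_boot = 500, seed = seed + 1)
cat(sprintf("Boldness repeatability r = %.2f +- %.2f (CI %.2f-%.2f; p = %.3g).\n",
            rb$r, rb$se, rb$ci[1], rb$ci[2], rb$p))

metrics <- read.csv("results/trip_metrics.csv")
mm <- metrics[, c("duration_h", "max_range_km", "max_lat_north", "max_lat_south")]
pca_f <- pca_correlation(mm, anchor = "max_range_km")
cat(sprintf("Foraging PCA: PC1 explains %.0f%% of trip-metric variance.\n",
            100 * pca_f$proportion[1]))
trip_score <- project_pc1(pca_f, mm)
foraging <- individual_foraging_score(trip_score, metrics$bird_id)
rf <- repeatability(fit_lmm_random_intercept(trip_score, group = metrics$bird_id),
                    n_boot = 500, seed = seed + 2)
cat(sprintf("Foraging repeatability r = %.2f +- %.2f (CI %.2f-%.2f; p = %.3g).\n",
            rf$r, rf$se, rf$ci[1], rf$ci[2], rf$p))

scores <- merge(boldness[, c("bird_id", "score")],
                foraging[, c("bird_id", "score")],
                by = "bird_id", suffixes = c("_boldness", "_foraging"))
write.csv(scores, "results/personality_scores.csv", row.names = FALSE)
syn <- score_correlation(scores$score_boldness, scores$score_foraging)
cat(sprintf("Boldness vs foraging score: Spearman rho = %.2f (p = %.3f, n = %d).\n",
            syn$rho, syn$p, syn$n))
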