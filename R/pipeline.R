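# sex-difference LRT on a score: mixed model with a bird random intercept
# when repeated measures exist, plain least squares otherwise
.sex_test_gaussian <- function(y, sex, bird) {
  sex <- factor(sex)
  if (any(duplicated(bird))) {
    full <- fit_lmm_random_intercept(y, data.frame(sex = sex), bird)
    red <- fit_lmm_random_intercept(y, group = bird)
    return(lrt(full, red))
  }
  f1 <- stats::lm(y ~ sex)
  f0 <- stats::lm(y ~ 1)
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(f1)) - as.numeric(stats::logLik(f0))))
  df <- length(stats::coef(f1)) - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates every stage end to end: data generation, trip segmentation
#' and phase filtering, trip metrics, FPT/ARS analysis, habitat
#' classification of ARS centres, fisheries-overlap models, PCA personality
#' scores with repeatability, the score correlation, and the fitness
#' models.  Per-stage artefacts are written as flat CSV/JSON under
#' `out_dir`, together with a run manifest (record counts and exclusion
#' bookkeeping per stage) and a summary table with one row per tested
#' effect (response, term, chi2, df, p, n).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param n_boot bootstrap replicates for repeatability intervals
#'   (default 200).
#' @param overlap_thin keep every k-th fix for the per-fix overlap GLMM
#'   (default 5, i.e. 10-minute resolution at 2-minute sampling).
#' @param radii FPT radius sweep, km.
#' @return invisible list with all stage results (`trips`, `metrics`,
#'   `fpt`, `zones`, `habitat`, `overlap`, `boldness`, `foraging`,
#'   `syndrome`, `fitness`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("boldtrack_run"),
                         n_boot = 200, overlap_thin = 5, radii = 1:100) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(started = fmt_utc(Sys.time()), seed = config$seed)
  summary_rows <- list()
  add_row <- function(response, term, test, n) {
    summary_rows[[length(summary_rows) + 1L]] <<- data.frame(
      response = response, term = term, chi2 = test$chi2, df = test$df,
      p = test$p, n = n, stringsAsFactors = FALSE)
  }
  on.exit({
    manifest$finished <- fmt_utc(Sys.time())
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  ## 1 -- simulate all inputs
  paths <- simulate_all(config, file.path(out_dir, "input"))
  sim <- attr(paths, "data")
  manifest$config_hash <- unname(tools::md5sum(paths$ground_truth))

  ## 2 -- trips: read, segment, phase-filter, metrics
  fixes <- read_gps_csv(paths$gps)
  manifest$fixes_read <- nrow(fixes)
  trips <- segment_trips(fixes, config$colony)
  trip_meta <- utils::read.csv(paths$trip_meta, stringsAsFactors = FALSE)
  trips <- assign_phase(trips, trip_meta)
  manifest$trips_segmented <- length(trips)
  brooding <- filter_phase(trips, "brooding")
  manifest$trips_excluded_phase <- length(trips) - length(brooding)
  brooding <- Filter(function(tr) isTRUE(tr$complete), brooding)
  manifest$trips_analysed <- length(brooding)
  metrics <- do.call(rbind, lapply(brooding, trip_metrics, colony = config$colony))
  utils::write.csv(metrics, file.path(out_dir, "trip_metrics.csv"), row.names = FALSE)

  ## 3 -- foraging personality: PCA on trip metrics, per-bird scores
  mm <- metrics[, c("duration_h", "max_range_km", "max_lat_north", "max_lat_south")]
  pca_f <- pca_correlation(mm, anchor = "max_range_km")
  trip_score <- project_pc1(pca_f, mm)
  foraging <- individual_foraging_score(trip_score, metrics$bird_id)
  fit_rf <- fit_lmm_random_intercept(trip_score, group = metrics$bird_id)
  rep_f <- repeatability(fit_rf, n_boot = n_boot, seed = substream(config$seed, 1L, 60L))
  birds <- utils::read.csv(paths$birds, stringsAsFactors = FALSE)
  sex_of <- function(id) birds$sex[match(id, birds$bird_id)]
  sex_test_f <- .sex_test_gaussian(trip_score, sex_of(metrics$bird_id),
                                   metrics$bird_id)
  add_row("foraging_personality", "sex", sex_test_f, nrow(foraging))

  ## 4 -- boldness: PCA on assay counts, per-bird scores
  beh <- utils::read.csv(paths$behaviour, stringsAsFactors = FALSE)
  bm <- beh[, c("peck_count", "lunge_count", "vocalise_count", "snap_count", "sitting_s")]
  pca_b <- pca_correlation(bm, anchor = "peck_count")
  obs_score <- project_pc1(pca_b, bm)
  boldness <- individual_boldness(obs_score, beh$bird_id, beh$obs_number,
                                  as.Date(beh$date))
  fit_rb <- fit_lmm_random_intercept(obs_score, group = beh$bird_id)
  rep_b <- repeatability(fit_rb, n_boot = n_boot, seed = substream(config$seed, 2L, 60L))
  tracked <- boldness[boldness$bird_id %in% birds$bird_id, ]
  tsel <- beh$bird_id %in% birds$bird_id
  add_row("boldness", "sex",
          .sex_test_gaussian(obs_score[tsel], sex_of(beh$bird_id[tsel]),
                             beh$bird_id[tsel]),
          nrow(tracked))

  ## 5 -- behavioural syndrome: correlation of the two scores
  common <- merge(boldness[, c("bird_id", "score")],
                  foraging[, c("bird_id", "score")],
                  by = "bird_id", suffixes = c("_bold", "_forage"))
  syndrome <- score_correlation(common$score_bold, common$score_forage)

  ## 6 -- FPT / ARS zones per trip, habitat at zone centres
  fpt_res <- lapply(brooding, analyse_trip_fpt, radii = radii)
  zones <- do.call(rbind, lapply(fpt_res, `[[`, "zones"))
  manifest$trips_fpt_skipped <- sum(vapply(fpt_res, `[[`, logical(1), "skipped"))
  manifest$ars_zones <- nrow(zones)
  zones$bird_id <- metrics$bird_id[match(zones$trip_id, metrics$trip_id)]
  zones$depth_m <- depth_at(sim$bathy, zones$centre_lat, zones$centre_lon)
  zones$habitat <- classify_habitat(zones$depth_m)
  utils::write.csv(zones, file.path(out_dir, "ars_zones.csv"), row.names = FALSE)
  peaks <- vapply(fpt_res, function(r) if (isTRUE(r$skipped)) NA_real_ else
    r$peak_radius_km, numeric(1))
  manifest$median_peak_radius_km <- stats::median(peaks, na.rm = TRUE)

  ## habitat ~ boldness + sex, ordinal with trip nested in bird
  hz <- zones[!is.na(zones$habitat), ]
  hz$boldness <- boldness$score[match(hz$bird_id, boldness$bird_id)]
  hz$sex <- sex_of(hz$bird_id)
  hz <- hz[stats::complete.cases(hz[, c("boldness", "sex")]), ]
  habitat_tests <- NULL
  if (nrow(hz) >= 20 && nlevels(droplevels(hz$habitat)) >= 2) {
    ord_full <- fit_ordinal(hz$habitat, data.frame(boldness = hz$boldness,
                                                   sex = factor(hz$sex)),
                            group = hz$bird_id, group2 = hz$trip_id)
    ord_nobold <- fit_ordinal(hz$habitat, data.frame(sex = factor(hz$sex)),
                              group = hz$bird_id, group2 = hz$trip_id)
    ord_nosex <- fit_ordinal(hz$habitat, data.frame(boldness = hz$boldness),
                             group = hz$bird_id, group2 = hz$trip_id)
    habitat_tests <- list(boldness = lrt(ord_full, ord_nobold),
                          sex = lrt(ord_full, ord_nosex), fit = ord_full)
    add_row("foraging_habitat", "boldness", habitat_tests$boldness,
            length(unique(hz$bird_id)))
    add_row("foraging_habitat", "sex", habitat_tests$sex, length(unique(hz$bird_id)))
  }

  ## 7 -- fisheries overlap
  dz <- build_discarding_zones(sim$fish)
  ov_sum <- do.call(rbind, lapply(brooding, trip_overlap_summary, zones = dz))
  utils::write.csv(ov_sum, file.path(out_dir, "overlap_summary.csv"), row.names = FALSE)
  bird_any <- tapply(ov_sum$any_overlap, ov_sum$bird_id, any)
  book <- overlap_bookkeeping(nrow(ov_sum), sum(ov_sum$any_overlap),
                              length(bird_any), sum(bird_any))
  manifest$trips_overlapping <- sum(ov_sum$any_overlap)
  manifest$birds_overlapping <- sum(bird_any)
  ov_fix <- do.call(rbind, lapply(brooding, function(tr) {
    f <- tr$fixes[seq(1, nrow(tr$fixes), by = overlap_thin), ]
    data.frame(trip_id = tr$trip_id, bird_id = tr$bird_id,
               overlap = fix_overlap(f$lat, f$lon, f$timestamp, dz),
               stringsAsFactors = FALSE)
  }))
  ov_fix$boldness <- boldness$score[match(ov_fix$bird_id, boldness$bird_id)]
  ov_fix$foraging <- foraging$score[match(ov_fix$bird_id, foraging$bird_id)]
  ov_fix$sex <- sex_of(ov_fix$bird_id)
  ovc <- ov_fix[stats::complete.cases(ov_fix), ]
  overlap_tests <- list()
  for (sc in c("boldness", "foraging")) {
    tests <- tryCatch({
      fx <- data.frame(score = ovc[[sc]], sex = factor(ovc$sex))
      full <- fit_glmm_binomial(ovc$overlap, cbind(fx, score_sex =
                                  fx$score * (fx$sex == "male")),
                                group = ovc$bird_id, group2 = ovc$trip_id)
      no_int <- fit_glmm_binomial(ovc$overlap, fx, group = ovc$bird_id,
                                  group2 = ovc$trip_id)
      no_score <- fit_glmm_binomial(ovc$overlap, fx["sex"], group = ovc$bird_id,
                                    group2 = ovc$trip_id)
      list(score = lrt(no_int, no_score), interaction = lrt(full, no_int))
    }, error = function(e) {
      manifest$overlap_model_failed[[sc]] <<- conditionMessage(e)
      NULL
    })
    if (is.null(tests)) next
    overlap_tests[[sc]] <- tests
    add_row("fisheries_overlap", sc, tests$score, length(unique(ovc$bird_id)))
    add_row("fisheries_overlap", paste0(sc, ":sex"), tests$interaction,
            length(unique(ovc$bird_id)))
  }

  ## 8 -- fitness: long-term fledging against each score
  scores_sex <- merge(boldness[, c("bird_id", "score")],
                      birds[, c("bird_id", "sex")], by = "bird_id")
  bre <- simulate_breeding(config, scores_sex)
  utils::write.csv(bre$breeding, file.path(out_dir, "breeding.csv"), row.names = FALSE)
  utils::write.csv(bre$ssta, file.path(out_dir, "ssta.csv"), row.names = FALSE)
  fit_bold <- tryCatch(fitness_analysis(bre$breeding, boldness, bre$ssta),
                       error = function(e) {
                         manifest$fitness_model_failed$boldness <<- conditionMessage(e)
                         NULL
                       })
  if (!is.null(fit_bold))
    add_row("fledging_success", "boldness:sex:ssta", fit_bold$interaction,
            length(unique(bre$breeding$bird_id)))
  fit_forage <- tryCatch(fitness_analysis(bre$breeding, foraging, bre$ssta),
                         error = function(e) {
                           manifest$fitness_model_failed$foraging <<- conditionMessage(e)
                           NULL
                         })
  if (!is.null(fit_forage))
    add_row("fledging_success", "foraging:sex:ssta", fit_forage$interaction,
            length(unique(fit_forage$data$bird_id)))

  ## summary + scores artefacts
  summary_tab <- do.call(rbind, summary_rows)
  utils::write.csv(summary_tab, file.path(out_dir, "summary_table.csv"),
                   row.names = FALSE)
  scores_out <- merge(boldness, foraging, by = "bird_id", all = TRUE,
                      suffixes = c("_boldness", "_foraging"))
  utils::write.csv(scores_out, file.path(out_dir, "personality_scores.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    repeatability_foraging = rep_f[c("r", "se", "ci", "p")],
    repeatability_boldness = rep_b[c("r", "se", "ci", "p")],
    pc1_proportion_boldness = pca_b$proportion[1],
    pc1_proportion_foraging = pca_f$proportion[1],
    syndrome = syndrome,
    overlap_bookkeeping = book),
    file.path(out_dir, "personality_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(paths = paths, trips = trips, brooding = brooding,
                 metrics = metrics, pca_foraging = pca_f, pca_boldness = pca_b,
                 foraging = foraging, boldness = boldness,
                 repeatability_foraging = rep_f, repeatability_boldness = rep_b,
                 syndrome = syndrome, fpt = fpt_res, zones = zones,
                 habitat_tests = habitat_tests, overlap_summary = ov_sum,
                 overlap_bookkeeping = book, overlap_tests = overlap_tests,
                 fitness_boldness = fit_bold, fitness_foraging = fit_forage,
                 summary = summary_tab, manifest = manifest))
}
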