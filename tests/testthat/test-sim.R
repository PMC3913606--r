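test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99)
  expect_identical(simulate_track(cfg, 3, 2), simulate_track(cfg, 3, 2))
  expect_identical(simulate_fishing_events(cfg, 12), simulate_fishing_events(cfg, 12))
  b1 <- simulate_behaviour(tiny_sim_config(seed = 99))
  b2 <- simulate_behaviour(tiny_sim_config(seed = 99))
  expect_identical(b1, b2)
  b3 <- simulate_behaviour(tiny_sim_config(seed = 100))
  expect_false(identical(b1$observations, b3$observations))
})

test_that("simulated trips dwell in their planted patch and return home", {
  frac <- vapply(1:5, function(k) {
    cfg <- sim_config(seed = 880 + k)
    trk <- simulate_track(cfg, 1, 1,
                          traits = list(pref_dist_km = 150, pref_bearing_deg = 90,
                                        incubating = FALSE))
    d <- haversine_km(trk$fixes$lat, trk$fixes$lon,
                      trk$patches$centre_lat[1], trk$patches$centre_lon[1])
    mean(d <= trk$patches$radius_km[1])
  }, numeric(1))
  expect_gte(mean(frac), 0.30)
  cfg <- sim_config(seed = 880)
  trk <- simulate_track(cfg, 1, 1)
  dc <- haversine_km(trk$fixes$lat, trk$fixes$lon, cfg$colony[1], cfg$colony[2])
  expect_lt(dc[1], 2)
  expect_lt(dc[length(dc)], 2)
  dt <- diff(as.numeric(trk$fixes$timestamp))
  expect_true(all(dt == cfg$fix_interval_s))
})

test_that("patch-free tracks yield no ARS zones in at least 90% of replicates", {
  none <- vapply(1:10, function(k) {
    cfg <- sim_config(seed = 700 + k, patch_count = 0L)
    trk <- simulate_track(cfg, 1, 1)
    res <- analyse_trip_fpt(list(trip_id = "t", bird_id = "b", fixes = trk$fixes))
    isTRUE(res$skipped) || nrow(res$zones) == 0
  }, logical(1))
  expect_gte(mean(none), 0.9)
})

test_that("bathymetry deepens monotonically and spans all habitat classes", {
  cfg <- sim_config(seed = 5)
  g <- simulate_bathymetry(cfg)
  expect_lt(depth_at(g, cfg$colony[1], cfg$colony[2]), 200)
  # radial transect at bearing 45 degrees: depths non-decreasing
  rr <- seq(5, 600, by = 5)
  pts <- boldtrack:::local_to_lonlat(rr * sin(pi / 4), rr * cos(pi / 4), cfg$colony)
  dd <- depth_at(g, pts$lat, pts$lon)
  expect_true(all(diff(dd) >= -1e-9))
  expect_gt(depth_at(g, pts$lat[100], pts$lon[100]), 2000)  # 500 km out
  expect_setequal(as.character(unique(classify_habitat(dd))),
                  c("shelf", "shelf_edge", "oceanic"))
})

test_that("fishing events sit on the shelf edge with valid time ordering", {
  cfg <- sim_config(seed = 6)
  ev <- simulate_fishing_events(cfg)
  expect_equal(nrow(ev), cfg$n_fishing_events)
  expect_true(all(ev$set_start < ev$set_end & ev$set_end <= ev$haul_start &
                    ev$haul_start < ev$haul_end))
  g <- simulate_bathymetry(cfg)
  d <- depth_at(g, ev$haul_lat, ev$haul_lon)
  expect_true(all(d >= 200 & d <= 2000))
  empty <- simulate_fishing_events(cfg, 0L)
  expect_equal(nrow(empty), 0)
  zones <- build_discarding_zones(empty)
  expect_false(any(fix_overlap(ev$haul_lat, ev$haul_lon, ev$haul_end, zones)))
})

test_that("attended events coincide with a bird's patch residence", {
  cfg <- tiny_sim_config(seed = 7, vessel_attend_prob = 1)
  gps <- simulate_gps(cfg)
  att <- simulate_attended_events(cfg, gps)
  expect_gt(nrow(att), 0)
  p <- gps$patches
  for (k in seq_len(nrow(att))) {
    dmin <- min(haversine_km(att$haul_lat[k], att$haul_lon[k],
                             p$centre_lat, p$centre_lon))
    expect_lt(dmin, 10)
    covered <- any(!is.na(p$t_enter) & att$haul_end[k] >= p$t_enter &
                     att$haul_end[k] <= p$t_exit)
    expect_true(covered)
  }
  expect_true(all(att$set_start < att$set_end & att$set_end <= att$haul_start &
                    att$haul_start < att$haul_end))
})

test_that("behaviour assay plants a recoverable latent ICC", {
  est_icc <- function(icc, seed) {
    cfg <- sim_config(seed = seed, n_behaviour_birds = 500L,
                      behaviour_repeat_fraction = 1, icc_boldness = icc)
    beh <- simulate_behaviour(cfg)$observations
    sc <- project_pc1(pca_correlation(
      beh[, c("peck_count", "lunge_count", "vocalise_count", "snap_count", "sitting_s")],
      anchor = "peck_count"),
      beh[, c("peck_count", "lunge_count", "vocalise_count", "snap_count", "sitting_s")])
    fit <- fit_lmm_random_intercept(sc, group = beh$bird_id)
    repeatability(fit, n_boot = 0)$r
  }
  expect_lt(abs(est_icc(0, 902)), 0.05)
  expect_lt(abs(est_icc(0.9, 905) - 0.9), 0.05)
})

test_that("zero observation noise gives identical counts across repeat tests", {
  cfg <- sim_config(seed = 8, n_behaviour_birds = 40L,
                    behaviour_repeat_fraction = 1, behaviour_noise = 0)
  obs <- simulate_behaviour(cfg)$observations
  for (b in unique(obs$bird_id)) {
    sub <- obs[obs$bird_id == b,
               c("peck_count", "lunge_count", "vocalise_count", "snap_count", "sitting_s")]
    expect_equal(sub[1, ], sub[2, ], ignore_attr = TRUE)
  }
})

test_that("breeding records follow the planted fledging model", {
  scores <- data.frame(bird_id = sprintf("b%03d", 1:59),
                       score = stats::rnorm(59),
                       sex = rep(c("female", "male"), length.out = 59))
  cfg0 <- sim_config(seed = 9, year_sd = 0, bird_sd = 0,
                     fledge_beta = c(intercept = 0, ssta = 0, sex = 0,
                                     score_female = 0, score_male = 0,
                                     score_ssta = 0, sex_ssta = 0,
                                     score_sex_ssta = 0))
  br <- simulate_breeding(cfg0, scores)
  expect_equal(mean(br$breeding$success), 0.5, tolerance = 0.04)
  expect_true(all(br$ssta$ssta > -0.60 & br$ssta$ssta < 0.13))
  expect_equal(nrow(br$breeding), 59 * cfg0$years)
  expect_identical(simulate_breeding(cfg0, scores), br)  # seeded reproducibility
  # all three year-quality bands are populated
  expect_setequal(as.character(unique(ssta_band(br$ssta$ssta))),
                  c("low", "medium", "high"))
})

test_that("generator configuration round-trips through YAML", {
  cfg <- sim_config(seed = 17, n_birds = 12L, icc_boldness = 0.7,
                    patch_dist_range_km = c(50, 90))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$seed, 17)
  expect_equal(cfg2$icc_boldness, 0.7)
  expect_equal(unname(cfg2$colony), unname(cfg$colony))
  expect_equal(unname(cfg2$patch_dist_range_km), c(50, 90))
  expect_equal(unname(cfg2$fledge_beta), unname(cfg$fledge_beta))
  expect_error(read_sim_config(
    withr::local_tempfile(lines = "icc_boldness: 1.4", fileext = ".yaml")),
    "icc")
})
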