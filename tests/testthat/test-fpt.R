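test_that("path interpolation places points every km with linear times", {
  tr <- straight_trip(total_km = 10, step_km = 2, speed_kmh = 60)
  p <- interpolate_path(tr)
  expect_equal(nrow(p), 11)
  expect_equal(p$dist_km, 0:10)
  dt <- diff(as.numeric(p$time))
  expect_equal(dt, rep(60, 10), tolerance = 1e-6)  # 1 km per minute
  # consecutive points ~1 km apart along the path
  gap <- haversine_km(p$lat[-11], p$lon[-11], p$lat[-1], p$lon[-1])
  expect_equal(gap, rep(1, 10), tolerance = 1e-4)
})

test_that("interpolation preserves corners and reversals", {
  # dog-leg on the equator: 3 km east then 4 km north -> 8 points,
  # corner preserved at cumdist 3
  t0 <- as.POSIXct("2011-12-25 00:00:00", tz = "UTC")
  dog <- list(trip_id = "dog", bird_id = "bX",
              fixes = data.frame(bird_id = "bX", trip_id = "dog",
                                 timestamp = t0 + c(0, 3, 7) * 90,
                                 lat = c(0, 0, 4 / KM_PER_DEG),
                                 lon = c(0, 3 / KM_PER_DEG, 3 / KM_PER_DEG)))
  p <- interpolate_path(dog)
  expect_equal(nrow(p), 8)
  expect_equal(p$lat[4] * KM_PER_DEG, 0, tolerance = 0.01)
  expect_equal(p$lon[4] * KM_PER_DEG, 3, tolerance = 0.01)

  # out-and-back 5 km along the equator: 11 points, the 6th at the turn
  oab <- list(trip_id = "oab", bird_id = "bX",
              fixes = data.frame(bird_id = "bX", trip_id = "oab",
                                 timestamp = t0 + c(0, 5, 10) * 90,
                                 lat = c(0, 0, 0),
                                 lon = c(0, 5 / KM_PER_DEG, 0)))
  p2 <- interpolate_path(oab)
  expect_equal(nrow(p2), 11)
  expect_equal(p2$lon[6] * KM_PER_DEG, 5, tolerance = 0.01)

  short <- straight_trip(total_km = 1.5, step_km = 0.5)
  expect_warning(expect_null(interpolate_path(short)), "shorter")
})

test_that("FPT on a straight constant-speed path is 2r/v", {
  tr <- straight_trip(total_km = 60, step_km = 2, speed_kmh = 50)
  p <- interpolate_path(tr)
  mid <- 31
  for (r in c(3, 7.5, 12)) {
    expect_equal(first_passage_time(p, mid, r), 2 * r / 50,
                 tolerance = 0.01)
  }
  # start and end points have no backward / forward exit
  expect_true(is.na(first_passage_time(p, 1, 5)))
  expect_true(is.na(first_passage_time(p, nrow(p), 5)))
  # radii wider than the reachable half-path are undefined everywhere
  prof <- fpt_profile(p, radii = c(5, 10, 31, 40))
  expect_true(all(is.na(prof$fpt[, 3])))
  expect_true(all(is.na(prof$fpt[, 4])))
})

test_that("FPT is non-decreasing in radius and the profile matches per-point calls", {
  cfg <- sim_config(seed = 301, patch_dist_range_km = c(60, 100), patch_dwell_h = 2)
  trk <- simulate_track(cfg, 1, 1)
  ft <- filter_on_water(list(trip_id = "t", bird_id = "b", fixes = trk$fixes))
  p <- interpolate_path(ft)
  radii <- c(2, 5, 10, 20, 40)
  prof <- fpt_profile(p, radii)
  for (i in seq(5, nrow(p) - 5, by = 17)) {
    row <- prof$fpt[i, ]
    expect_equal(row, first_passage_time(p, i, radii))
    dd <- diff(row[!is.na(row)])
    expect_true(all(dd >= -1e-9))
  }
})

test_that("interpolated-crossing FPT matches the dense brute-force oracle", {
  cfg <- sim_config(seed = 302, patch_dist_range_km = c(60, 100), patch_dwell_h = 2)
  trk <- simulate_track(cfg, 1, 1)
  ft <- filter_on_water(list(trip_id = "t", bird_id = "b", fixes = trk$fixes))
  p <- interpolate_path(ft)
  set.seed(302)
  for (i in sample(5:(nrow(p) - 5), 6)) {
    for (r in c(3, 8, 15)) {
      a <- first_passage_time(p, i, r)
      b <- fpt_brute(p, i, r)
      if (is.na(a) || is.na(b)) {
        expect_true(is.na(a) && is.na(b))
      } else {
        expect_equal(a, b, tolerance = 0.01)
      }
    }
  }
})

test_that("log-FPT variance is flat on a uniform path and undefined when sparse", {
  tr <- straight_trip(total_km = 60, step_km = 2, speed_kmh = 50)
  p <- interpolate_path(tr)
  prof <- fpt_profile(p, radii = 1:20)
  s <- variance_curve(prof)
  expect_true(all(s[!is.na(s)] < 1e-3))
  # a radius with fewer than 5 defined points yields NA
  prof$fpt[6:nrow(p), 3] <- NA
  expect_true(is.na(variance_curve(prof)[3]))
})

test_that("peak detection finds interior maxima above both floors", {
  r <- 1:40
  unimodal <- 0.8 * exp(-(r - 12)^2 / 30)
  pk <- detect_peaks(unimodal, r)
  expect_equal(pk$radius_km, 12)
  expect_length(detect_peaks(rep(0.5, 40), r)$radius_km, 0)    # flat: no peak
  expect_length(detect_peaks(unimodal / 100, r)$radius_km, 0)  # below floor
  # two scales: both reported, ordered by variance
  bimodal <- 0.9 * exp(-(r - 6)^2 / 8) + 0.7 * exp(-(r - 30)^2 / 20)
  pk2 <- detect_peaks(bimodal, r)
  expect_equal(sort(pk2$radius_km), c(6, 30))
  expect_gte(pk2$variance[1], pk2$variance[2])
  # plateau ties break toward the smaller radius
  plat <- c(0.1, 0.5, 0.5, 0.1, rep(0.05, 36))
  expect_equal(detect_peaks(plat, r)$radius_km, 2)
})

test_that("Otsu threshold splits bimodal FPT samples like exhaustive search", {
  bi <- c(rep(1, 4), rep(10, 4))
  th <- fpt_threshold(bi, min_values = 8)
  expect_gt(th, 1); expect_lt(th, 10)
  set.seed(41)
  for (k in 1:10) {
    v <- exp(c(stats::rnorm(15, 0, 0.3), stats::rnorm(12, 2, 0.4)))
    expect_equal(fpt_threshold(v), otsu_brute(v))
  }
  # unimodal tight sample: threshold near the middle, zones bounded
  u <- exp(stats::rnorm(50, 1, 0.1))
  tu <- fpt_threshold(u)
  expect_lte(mean(u > tu), 0.5)
  expect_error(fpt_threshold(1:5), "fewer than")
})

test_that("ARS zones form above threshold and merge below 10 km separation", {
  # synthetic profile on a straight 1-km-spaced path
  tr <- straight_trip(total_km = 40, step_km = 2, speed_kmh = 50)
  p <- interpolate_path(tr)
  prof <- structure(list(fpt = matrix(1, nrow(p), 1), radii = 5, path = p),
                    class = "fpt_profile")
  expect_equal(nrow(extract_ars_zones(prof, 5, 2, trip_id = "t")), 0)
  # two runs with centres 8 km apart -> merged into one zone
  prof$fpt[9:12, 1] <- 10    # centre near km 9.5
  prof$fpt[17:20, 1] <- 10   # centre near km 17.5
  z8 <- extract_ars_zones(prof, 5, 2, min_sep_km = 10, trip_id = "t")
  expect_equal(nrow(z8), 1)
  expect_equal(z8$n_points, 8)
  # same runs, 16 km apart -> two zones, separation verified
  prof$fpt[, 1] <- 1
  prof$fpt[5:8, 1] <- 10
  prof$fpt[19:22, 1] <- 10
  z16 <- extract_ars_zones(prof, 5, 2, min_sep_km = 10, trip_id = "t")
  expect_equal(nrow(z16), 2)
  dd <- haversine_km(z16$centre_lat[1], z16$centre_lon[1],
                     z16$centre_lat[2], z16$centre_lon[2])
  expect_gt(dd, 10)
})

test_that("zone centres stay pairwise separated after merging on real tracks", {
  for (seed in c(601, 602)) {
    cfg <- sim_config(seed = seed, patch_count = 2L)
    trk <- simulate_track(cfg, 1, 1)
    res <- analyse_trip_fpt(list(trip_id = "t", bird_id = "b", fixes = trk$fixes))
    if (isTRUE(res$skipped) || nrow(res$zones) < 2) next
    cen <- res$zones
    for (a in 1:(nrow(cen) - 1)) for (b in (a + 1):nrow(cen)) {
      expect_gt(haversine_km(cen$centre_lat[a], cen$centre_lon[a],
                             cen$centre_lat[b], cen$centre_lon[b]), 10)
    }
  }
})
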