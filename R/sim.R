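#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study design the pipeline is built for: a
#' black-browed-albatross colony at 48.4 S, 68.4 E; GPS fixes every two
#' minutes over brooding-season trips; a shelf that deepens radially from
#' the colony with the shelf edge (200-2000 m) between `shelf_km` and
#' `break_km`; longliners hauling on the shelf edge; a novel-object assay
#' on 154 birds with ~10% retested; and 23 breeding seasons whose
#' September-November SSTa values span the low/medium/high year-quality
#' bands (-0.60 to 0.13 deg C).
#'
#' @param seed root seed; all generator streams derive from it.
#' @param colony c(lat, lon), decimal degrees.
#' @param n_birds number of GPS-tracked birds.
#' @param trips_per_bird foraging trips recorded per bird.
#' @param fix_interval_s GPS sampling interval, seconds.
#' @param patch_count planted prey patches per trip.
#' @param patch_radius_km patch radius (recycled over patches), km.
#' @param patch_dist_range_km range of patch distances from the colony, km.
#' @param commute_speed_kmh,forage_speed_kmh flight speeds in the two
#'   movement states, km/h.  The forage speed stays above the 10 km/h
#'   on-water filter: it represents slow sinuous search flight, with
#'   sitting on the water excluded upstream.
#' @param turn_sd_commute_deg,turn_sd_forage_deg wrapped-normal turning-angle
#'   standard deviations per step (high directional persistence while
#'   commuting, low while foraging).
#' @param patch_dwell_h mean residence time per patch, hours.
#' @param icc_boldness,icc_foraging latent intra-class correlations planted
#'   in the boldness assay and the trip-metric latent, in [0, 1).
#' @param boldness_foraging_cor correlation between the bird-level boldness
#'   latent and the foraging-distance latent (negative: bolder birds forage
#'   nearer the colony).
#' @param behaviour_loading loading of each behavioural variable on the
#'   observation latent (Gaussian copula).
#' @param behaviour_noise 0 disables all observation-level noise (counts
#'   become a deterministic function of the bird latent).
#' @param sex_ratio probability a bird is female.
#' @param sex_effect_dist_km extra preferred foraging distance for females,
#'   km (females make longer, more northerly trips).
#' @param n_behaviour_birds birds given the novel-object assay.
#' @param behaviour_repeat_fraction fraction of assayed birds tested twice.
#' @param years breeding seasons in the long-term record.
#' @param n_breeding_birds birds with known personality in that record.
#' @param fledge_beta named log-odds effects for the fledging model:
#'   intercept, ssta, sex, score_female, score_male, score_ssta, sex_ssta,
#'   score_sex_ssta (the score slopes are per sex; ssta enters centred).
#' @param year_sd,bird_sd random year/bird effect SDs on the fledging
#'   log-odds.
#' @param incubation_fraction probability a bird's trips are late-incubation
#'   (longer) rather than brooding trips.
#' @param shelf_km,break_km radial distances where depth reaches 200 m and
#'   2000 m.
#' @param n_fishing_events background longline events during the tracking
#'   window.
#' @param vessel_attend_prob probability that a trip whose prey patch lies
#'   on the shelf edge is an aggregation at a discarding vessel (an
#'   additional fishing event is placed at that patch during the bird's
#'   residence); albatross aggregate at longliners during discarding, and
#'   vessels work the shelf edge, so attendance is conditional on foraging
#'   there.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       colony = c(lat = -48.4, lon = 68.4),
                       n_birds = 69L,
                       trips_per_bird = 3L,
                       fix_interval_s = 120,
                       patch_count = 1L,
                       patch_radius_km = 5,
                       patch_dist_range_km = c(80, 250),
                       commute_speed_kmh = 50,
                       forage_speed_kmh = 15,
                       turn_sd_commute_deg = 15,
                       turn_sd_forage_deg = 75,
                       patch_dwell_h = 4,
                       icc_boldness = 0.5,
                       icc_foraging = 0.5,
                       boldness_foraging_cor = -0.45,
                       behaviour_loading = 0.95,
                       behaviour_noise = 1,
                       sex_ratio = 0.5,
                       sex_effect_dist_km = 30,
                       n_behaviour_birds = 154L,
                       behaviour_repeat_fraction = 16 / 154,
                       years = 23L,
                       n_breeding_birds = 59L,
                       fledge_beta = c(intercept = 0.3, ssta = 1.2, sex = 0,
                                       score_female = 0.5, score_male = -0.5,
                                       score_ssta = 0.8, sex_ssta = 0,
                                       score_sex_ssta = 0),
                       year_sd = 0.3,
                       bird_sd = 0.3,
                       incubation_fraction = 0.08,
                       shelf_km = 150,
                       break_km = 250,
                       n_fishing_events = 60L,
                       vessel_attend_prob = 0.4) {
  cfg <- as.list(environment())
  if (cfg$fix_interval_s <= 0) stop("fix_interval_s must be > 0")
  if (cfg$commute_speed_kmh <= 0 || cfg$forage_speed_kmh <= 0)
    stop("speeds must be > 0")
  if (any(cfg$patch_radius_km <= 0)) stop("patch_radius_km must be > 0")
  if (cfg$icc_boldness < 0 || cfg$icc_boldness >= 1 ||
      cfg$icc_foraging < 0 || cfg$icc_foraging >= 1)
    stop("icc values must lie in [0, 1)")
  if (cfg$patch_dwell_h <= 0) stop("patch_dwell_h must be > 0")
  if (cfg$break_km <= cfg$shelf_km) stop("break_km must exceed shelf_km")
  structure(cfg, class = "sim_config")
}

#' Read / write a generator configuration as YAML
#'
#' A plain-text key/value file mirroring [sim_config()]; vector-valued
#' fields (colony, patch distance range, effect sizes) round-trip with
#' their names.
#'
#' @param path YAML file.
#' @return for `read_sim_config`, a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("colony", "patch_dist_range_km", "fledge_beta"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(lapply(unclass(config), function(v)
    if (!is.null(names(v))) as.list(v) else v), path)
  invisible(path)
}

# deterministic substream seed below 2^31
substream <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 9973 + j * 101 + 17) %% 2147483647)
}

study_start <- function() as.POSIXct("2011-12-20 00:00:00", tz = "UTC")

# per-bird latent streams, shared across generator stages so that the
# behavioural and foraging latents can be correlated
.bird_boldness_latent <- function(config, i) {
  set.seed(substream(config$seed, i, 500L))
  stats::rnorm(1)
}

.bird_forage_latent <- function(config, i) {
  z <- .bird_boldness_latent(config, i)
  set.seed(substream(config$seed, i, 501L))
  e <- stats::rnorm(1)
  rho <- config$boldness_foraging_cor
  rho * z + sqrt(1 - rho^2) * e
}

#' Simulate one foraging trip as a two-state correlated random walk
#'
#' The bird leaves the colony, commutes with high directional persistence
#' toward a planted prey patch, switches inside the patch to slow sinuous
#' search (low persistence, reflected back at the patch edge), and after
#' its residence time commutes onward or home.  Fixes are recorded every
#' `fix_interval_s` seconds; the trip starts and ends at the colony.
#'
#' @param config a `sim_config`.
#' @param bird_id,trip_index identify the trip (and its RNG substream).
#' @param start_time POSIXct of the first fix.
#' @param traits optional list(pref_dist_km, pref_bearing_deg, incubating)
#'   from the bird-level generator; defaults drawn from config otherwise.
#' @return list `fixes` (data.frame lat/lon/timestamp), `patches`
#'   (data.frame centre_lat/centre_lon/radius_km), `phase`.
#' @export
simulate_track <- function(config, bird_id = 1L, trip_index = 1L,
                           start_time = study_start(), traits = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream(config$seed, bird_id, trip_index))
  colony <- config$colony
  dt_h <- config$fix_interval_s / 3600
  if (is.null(traits)) {
    traits <- list(pref_dist_km = mean(config$patch_dist_range_km),
                   pref_bearing_deg = stats::runif(1, 0, 180),
                   incubating = FALSE)
  }
  mult <- if (isTRUE(traits$incubating)) 1.8 else 1
  n_patch <- config$patch_count
  radii <- rep_len(config$patch_radius_km, max(1, n_patch))
  patches <- NULL
  if (n_patch > 0) {
    pd <- traits$pref_dist_km * mult * seq_len(n_patch) / n_patch +
      stats::rnorm(n_patch, 0, 10)
    pd <- pmax(pd, 30)
    pb <- (traits$pref_bearing_deg + stats::rnorm(n_patch, 0, 12)) * pi / 180
    patches <- data.frame(x = pd * sin(pb), y = pd * cos(pb),
                          radius_km = radii[seq_len(n_patch)])
  }
  sd_c <- config$turn_sd_commute_deg * pi / 180
  sd_f <- config$turn_sd_forage_deg * pi / 180
  step_c <- config$commute_speed_kmh * dt_h
  step_f <- config$forage_speed_kmh * dt_h
  x <- 0; y <- 0
  xs <- x; ys <- y
  heading <- if (n_patch > 0) atan2(patches$x[1], patches$y[1]) else
    stats::runif(1, 0, 2 * pi)
  target <- 1L                     # next patch index; > n_patch means colony
  state <- "commute"
  dwell_left <- 0
  max_steps <- 6000L
  for (s in seq_len(max_steps)) {
    if (state == "commute") {
      tx <- if (n_patch > 0 && target <= n_patch) patches$x[target] else 0
      ty <- if (n_patch > 0 && target <= n_patch) patches$y[target] else 0
      bear <- atan2(tx - x, ty - y)
      dh <- ((bear - heading + pi) %% (2 * pi)) - pi
      heading <- heading + 0.35 * dh + stats::rnorm(1, 0, sd_c)
      x <- x + step_c * sin(heading)
      y <- y + step_c * cos(heading)
      if (n_patch > 0 && target <= n_patch) {
        if (sqrt((x - patches$x[target])^2 + (y - patches$y[target])^2) <
            0.6 * patches$radius_km[target]) {
          state <- "forage"
          dwell_left <- config$patch_dwell_h * mult * exp(stats::rnorm(1, 0, 0.15))
        }
      } else if (sqrt(x^2 + y^2) < max(step_c, 2)) {
        # home: first fix back inside the colony buffer ends the trip
        xs <- c(xs, 0); ys <- c(ys, 0)
        break
      }
    } else {
      heading <- heading + stats::rnorm(1, 0, sd_f)
      xn <- x + step_f * sin(heading)
      yn <- y + step_f * cos(heading)
      if (sqrt((xn - patches$x[target])^2 + (yn - patches$y[target])^2) >
          patches$radius_km[target]) {
        heading <- atan2(patches$x[target] - x, patches$y[target] - y) +
          stats::rnorm(1, 0, 0.5)
        xn <- x + step_f * sin(heading)
        yn <- y + step_f * cos(heading)
      }
      x <- xn; y <- yn
      dwell_left <- dwell_left - dt_h
      if (dwell_left <= 0) {
        state <- "commute"
        target <- target + 1L
      }
    }
    xs <- c(xs, x); ys <- c(ys, y)
  }
  ll <- local_to_lonlat(xs, ys, colony)
  fixes <- data.frame(
    bird_id = sprintf("b%03d", bird_id),
    trip_id = sprintf("b%03d_t%d", bird_id, trip_index),
    timestamp = start_time + (seq_along(xs) - 1) * config$fix_interval_s,
    lat = ll$lat, lon = ll$lon,
    stringsAsFactors = FALSE
  )
  pl <- if (!is.null(patches)) {
    pll <- local_to_lonlat(patches$x, patches$y, colony)
    out <- data.frame(centre_lat = pll$lat, centre_lon = pll$lon,
                      radius_km = patches$radius_km,
                      dist_km = sqrt(patches$x^2 + patches$y^2))
    # realised residence window per patch (first/last fix inside the circle)
    out$t_enter <- as.POSIXct(NA, tz = "UTC")
    out$t_exit <- as.POSIXct(NA, tz = "UTC")
    for (k in seq_len(nrow(out))) {
      inside <- which(haversine_km(fixes$lat, fixes$lon,
                                   out$centre_lat[k], out$centre_lon[k]) <=
                        out$radius_km[k])
      if (length(inside)) {
        out$t_enter[k] <- fixes$timestamp[inside[1]]
        out$t_exit[k] <- fixes$timestamp[inside[length(inside)]]
      }
    }
    out
  } else {
    data.frame(centre_lat = numeric(0), centre_lon = numeric(0),
               radius_km = numeric(0), dist_km = numeric(0),
               t_enter = as.POSIXct(character(0), tz = "UTC"),
               t_exit = as.POSIXct(character(0), tz = "UTC"))
  }
  list(fixes = fixes,
       patches = pl,
       phase = if (isTRUE(traits$incubating)) "incubation" else "brooding")
}

#' Simulate the full GPS data set (all birds, all trips)
#'
#' Bird-level traits give each individual a preferred foraging distance and
#' bearing; the between-bird share of distance variance is `icc_foraging`,
#' so downstream trip metrics carry a recoverable foraging-personality
#' signal.  Females are given longer preferred distances and more northerly
#' bearings.  A fraction of birds is in late incubation (longer trips,
#' phase-flagged).  At-colony fixes are inserted between trips so trip
#' segmentation can be exercised on the raw fix table.
#'
#' @param config a `sim_config`.
#' @return list `fixes` (all birds), `trip_meta` (trip_id, bird_id, phase,
#'   patch centres), `birds` (bird_id, sex, latent traits), `patches`
#'   (per-trip planted patches), `ground_truth`.
#' @export
simulate_gps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream(config$seed, 0L, 1L))
  n <- config$n_birds
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "female", "male")
  lat_b <- stats::rnorm(n)                    # bird latent: bearing preference
  # foraging-distance latent, correlated with the boldness latent
  lat_f <- vapply(seq_len(n), function(i) .bird_forage_latent(config, i), numeric(1))
  incub <- stats::runif(n) < config$incubation_fraction
  base_d <- mean(config$patch_dist_range_km)
  spread <- diff(config$patch_dist_range_km) / 4
  birds <- data.frame(
    bird_id = sprintf("b%03d", seq_len(n)),
    sex = sex,
    latent_dist = lat_f,
    pref_dist_km = pmin(pmax(base_d + (sex == "female") * config$sex_effect_dist_km +
                               spread * sqrt(config$icc_foraging) * lat_f,
                             config$patch_dist_range_km[1]),
                        config$patch_dist_range_km[2] * 1.3),
    pref_bearing_deg = pmin(pmax(90 - (sex == "female") * 35 + 28 * lat_b, -20), 200),
    incubating = incub,
    stringsAsFactors = FALSE
  )
  all_fixes <- vector("list", n)
  meta <- vector("list", n)
  patch_list <- list()
  for (b in seq_len(n)) {
    set.seed(substream(config$seed, b, 900L))
    t0 <- study_start() + stats::runif(1, 0, 3 * 86400)
    bf <- list(); bm <- list()
    for (tr in seq_len(config$trips_per_bird)) {
      set.seed(substream(config$seed, b, 800L + tr))
      trip_d <- pmax(birds$pref_dist_km[b] +
                       stats::rnorm(1, 0, spread * sqrt(1 - config$icc_foraging)), 40)
      traits <- list(pref_dist_km = trip_d,
                     pref_bearing_deg = birds$pref_bearing_deg[b] + stats::rnorm(1, 0, 25),
                     incubating = birds$incubating[b])
      # at-colony fixes before the trip (rest period)
      n_col <- 5L
      jit <- local_to_lonlat(stats::rnorm(n_col, 0, 0.15), stats::rnorm(n_col, 0, 0.15),
                             config$colony)
      col_fix <- data.frame(
        bird_id = sprintf("b%03d", b),
        trip_id = NA_character_,
        timestamp = t0 + (seq_len(n_col) - 1) * config$fix_interval_s,
        lat = jit$lat, lon = jit$lon, stringsAsFactors = FALSE)
      t0 <- t0 + n_col * config$fix_interval_s
      trk <- simulate_track(config, b, tr, t0, traits)
      bf[[length(bf) + 1L]] <- col_fix
      bf[[length(bf) + 1L]] <- trk$fixes
      tid <- trk$fixes$trip_id[1]
      bm[[length(bm) + 1L]] <- data.frame(trip_id = tid,
                                          bird_id = sprintf("b%03d", b),
                                          phase = trk$phase,
                                          stringsAsFactors = FALSE)
      if (nrow(trk$patches)) {
        pk <- trk$patches; pk$trip_id <- tid
        patch_list[[length(patch_list) + 1L]] <- pk
      }
      set.seed(substream(config$seed, b, 700L + tr))
      rest_h <- stats::runif(1, 6, 20)
      t0 <- max(trk$fixes$timestamp) + rest_h * 3600
    }
    # trailing colony fixes so the last trip is complete
    jit <- local_to_lonlat(stats::rnorm(3, 0, 0.15), stats::rnorm(3, 0, 0.15),
                           config$colony)
    bf[[length(bf) + 1L]] <- data.frame(
      bird_id = sprintf("b%03d", b), trip_id = NA_character_,
      timestamp = t0 + (1:3) * config$fix_interval_s,
      lat = jit$lat, lon = jit$lon, stringsAsFactors = FALSE)
    all_fixes[[b]] <- do.call(rbind, bf)
    meta[[b]] <- do.call(rbind, bm)
  }
  fixes <- do.call(rbind, all_fixes)
  trip_meta <- do.call(rbind, meta)
  patches <- if (length(patch_list)) do.call(rbind, patch_list) else
    data.frame(centre_lat = numeric(0), centre_lon = numeric(0),
               radius_km = numeric(0), trip_id = character(0))
  list(fixes = fixes, trip_meta = trip_meta, birds = birds, patches = patches,
       ground_truth = list(icc_foraging = config$icc_foraging,
                           sex_effect_dist_km = config$sex_effect_dist_km,
                           patches = patches))
}

#' Synthetic radial bathymetry around the colony
#'
#' Depth increases monotonically with great-circle distance from the
#' colony: a shallow shelf out to `shelf_km` (20-200 m), a shelf edge
#' deepening to 2000 m at `break_km`, then an abyssal slope capped at
#' 5500 m, so all three habitat classes exist.
#'
#' @param config a `sim_config`.
#' @param cell_deg grid resolution in degrees (default 0.1).
#' @param margin_km extra extent beyond the furthest plausible track, km.
#' @return a `bathy_grid` (see [read_bathymetry()]).
#' @export
simulate_bathymetry <- function(config, cell_deg = 0.1, margin_km = 150) {
  stopifnot(inherits(config, "sim_config"))
  reach <- config$patch_dist_range_km[2] * 1.3 * 1.8 + margin_km
  km_deg <- 6371 * pi / 180
  dlat <- reach / km_deg
  dlon <- reach / (km_deg * cos(config$colony[[1]] * pi / 180))
  yll <- config$colony[[1]] - dlat
  xll <- config$colony[[2]] - dlon
  nrows <- ceiling(2 * dlat / cell_deg)
  ncols <- ceiling(2 * dlon / cell_deg)
  lat_c <- yll + (seq_len(nrows) - 0.5) * cell_deg        # south -> north
  lon_c <- xll + (seq_len(ncols) - 0.5) * cell_deg
  depth_of <- function(r) {
    ifelse(r <= config$shelf_km, 20 + 180 * r / config$shelf_km,
           ifelse(r <= config$break_km,
                  200 + 1800 * (r - config$shelf_km) / (config$break_km - config$shelf_km),
                  pmin(2000 + 3 * (r - config$break_km), 5500)))
  }
  depth <- matrix(NA_real_, nrows, ncols)                  # rows north -> south
  for (i in seq_len(nrows)) {
    la <- lat_c[nrows - i + 1]
    depth[i, ] <- depth_of(haversine_km(la, lon_c, config$colony[[1]], config$colony[[2]]))
  }
  structure(list(ncols = ncols, nrows = nrows, xllcorner = xll, yllcorner = yll,
                 cellsize = cell_deg, nodata = -9999, depth = depth),
            class = "bathy_grid")
}

#' Simulate longline fishing events on the shelf edge
#'
#' Haul-end points fall at radial distances where depth is 200-2000 m
#' (vessels work the shelf edge); events are spread over the tracking
#' window, with lines set overnight and hauled hours later.
#'
#' @param config a `sim_config`.
#' @param n_events number of events (default `config$n_fishing_events`).
#' @return data.frame in the fishing-event schema (see [read_fishing_csv()]).
#' @export
simulate_fishing_events <- function(config, n_events = config$n_fishing_events) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream(config$seed, 0L, 2L))
  if (n_events == 0) {
    return(data.frame(line_id = character(0), set_start = as.POSIXct(character(0), tz = "UTC"),
                      set_end = as.POSIXct(character(0), tz = "UTC"),
                      haul_start = as.POSIXct(character(0), tz = "UTC"),
                      haul_end = as.POSIXct(character(0), tz = "UTC"),
                      set_lat = numeric(0), set_lon = numeric(0),
                      haul_lat = numeric(0), haul_lon = numeric(0)))
  }
  r <- stats::runif(n_events, config$shelf_km + 20, config$break_km - 20)
  bear <- stats::runif(n_events, 0, 180) * pi / 180
  haul <- local_to_lonlat(r * sin(bear), r * cos(bear), config$colony)
  off <- local_to_lonlat(r * sin(bear) + stats::rnorm(n_events, 0, 4),
                         r * cos(bear) + stats::rnorm(n_events, 0, 4), config$colony)
  haul_end <- study_start() + stats::runif(n_events, 0, 34 * 86400)
  haul_start <- haul_end - stats::runif(n_events, 2, 4) * 3600
  set_end <- haul_start - stats::runif(n_events, 4, 8) * 3600
  set_start <- set_end - stats::runif(n_events, 3, 5) * 3600
  data.frame(line_id = sprintf("L%03d", seq_len(n_events)),
             set_start = set_start, set_end = set_end,
             haul_start = haul_start, haul_end = haul_end,
             set_lat = off$lat, set_lon = off$lon,
             haul_lat = haul$lat, haul_lon = haul$lon,
             stringsAsFactors = FALSE)
}

#' Fishing events attended by foraging birds
#'
#' Albatross aggregate at longliners while offal is discarded, so a share
#' of shelf-edge foraging patches are in fact vessels: for each trip whose
#' planted patch lies on the shelf edge, with probability
#' `vessel_attend_prob` an additional fishing event is created whose
#' haul-end position sits at the patch and whose discarding window falls
#' inside the bird's residence time there.
#'
#' @param config a `sim_config`.
#' @param gps result of [simulate_gps()].
#' @return data.frame in the fishing-event schema (possibly zero rows).
#' @export
simulate_attended_events <- function(config, gps) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream(config$seed, 0L, 5L))
  p <- gps$patches
  if (!nrow(p)) return(simulate_fishing_events(config, 0L))
  res_h <- as.numeric(p$t_exit) - as.numeric(p$t_enter)
  eligible <- which(!is.na(res_h) & res_h / 3600 >= 1.5 &
                      p$dist_km > config$shelf_km + 10 &
                      p$dist_km < config$break_km - 10)
  eligible <- eligible[!duplicated(p$trip_id[eligible])]
  take <- eligible[stats::runif(length(eligible)) < config$vessel_attend_prob]
  if (!length(take)) return(simulate_fishing_events(config, 0L))
  km_deg <- 6371 * pi / 180
  lat <- p$centre_lat[take] + stats::rnorm(length(take), 0, 2 / km_deg)
  lon <- p$centre_lon[take] + stats::rnorm(length(take), 0, 2 / km_deg)
  haul_end <- p$t_enter[take] + 0.3 * (as.numeric(p$t_exit[take]) -
                                         as.numeric(p$t_enter[take]))
  haul_start <- haul_end - stats::runif(length(take), 2, 4) * 3600
  set_end <- haul_start - stats::runif(length(take), 4, 8) * 3600
  set_start <- set_end - stats::runif(length(take), 3, 5) * 3600
  data.frame(line_id = sprintf("A%03d", seq_along(take)),
             set_start = set_start, set_end = set_end,
             haul_start = haul_start, haul_end = haul_end,
             set_lat = lat, set_lon = lon,
             haul_lat = lat, haul_lon = lon,
             stringsAsFactors = FALSE)
}

#' Simulate the novel-object behaviour assay
#'
#' Each bird has a latent boldness; each observation adds within-bird
#' noise so that the between-bird share of latent variance equals
#' `icc_boldness`.  The five recorded variables (pecks, lunges,
#' vocalisations, snaps, seconds sitting in the scored 30-s window) load on
#' the observation latent through a Gaussian copula: pecking, lunging and
#' vocalising increase with boldness, snapping and sitting decrease.
#'
#' @param config a `sim_config`.
#' @return list `observations` (bird_id, obs_number, date, peck_count,
#'   lunge_count, vocalise_count, snap_count, sitting_s) and
#'   `latent` (bird_id, boldness latent).
#' @export
simulate_behaviour <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream(config$seed, 0L, 3L))
  n <- config$n_behaviour_birds
  ids <- sprintf("b%03d", seq_len(n))
  z <- vapply(seq_len(n), function(i) .bird_boldness_latent(config, i), numeric(1))
  set.seed(substream(config$seed, 0L, 3L))
  n_rep <- round(config$behaviour_repeat_fraction * n)
  repeated <- sample(n, n_rep)
  rows <- data.frame(bird = rep(seq_len(n), times = 1 + seq_len(n) %in% repeated))
  rows <- rows[order(rows$bird), , drop = FALSE]
  rows$obs_number <- stats::ave(rows$bird, rows$bird, FUN = seq_along)
  noise <- config$behaviour_noise
  icc <- config$icc_boldness
  m <- nrow(rows)
  l_obs <- sqrt(icc) * z[rows$bird] +
    noise * sqrt(1 - icc) * stats::rnorm(m)
  rho <- config$behaviour_loading
  vnoise <- function() noise * sqrt(1 - rho^2) * stats::rnorm(m)
  v_peck <- rho * l_obs + vnoise()
  v_lunge <- rho * l_obs + vnoise()
  v_voc <- rho * l_obs + vnoise()
  v_snap <- -rho * l_obs + vnoise()
  v_sit <- -rho * l_obs + vnoise()
  date0 <- as.Date("2011-12-20")
  d1 <- date0 + sample(0:20, n, replace = TRUE)
  obs_date <- as.Date(ifelse(rows$obs_number == 1, d1[rows$bird],
                             d1[rows$bird] + 7 + sample(0:7, m, replace = TRUE)),
                      origin = "1970-01-01")
  observations <- data.frame(
    bird_id = ids[rows$bird],
    obs_number = rows$obs_number,
    date = obs_date,
    peck_count = stats::qpois(stats::pnorm(v_peck / sqrt(ifelse(noise > 0, 1, rho^2))), 8),
    lunge_count = stats::qpois(stats::pnorm(v_lunge / sqrt(ifelse(noise > 0, 1, rho^2))), 6),
    vocalise_count = stats::qpois(stats::pnorm(v_voc / sqrt(ifelse(noise > 0, 1, rho^2))), 10),
    snap_count = stats::qpois(stats::pnorm(v_snap / sqrt(ifelse(noise > 0, 1, rho^2))), 5),
    sitting_s = round(30 * stats::plogis(1.2 * v_sit)),
    stringsAsFactors = FALSE
  )
  list(observations = observations,
       latent = data.frame(bird_id = ids, boldness = z, stringsAsFactors = FALSE))
}

#' Simulate yearly SSTa values and long-term fledging records
#'
#' SSTa values are drawn uniformly within the three year-quality bands
#' (low: -0.60 to -0.36; medium: -0.36 to -0.15; high: -0.15 to 0.13),
#' with years allocated to bands as evenly as possible.  Fledging success
#' is Bernoulli with log-odds given by the configured effect sizes: sex-
#' specific score slopes modulated by centred SSTa, plus random bird and
#' year effects.
#'
#' @param config a `sim_config`.
#' @param scores data.frame with `bird_id`, `score` (mean-centred), `sex`.
#' @return list `breeding` (bird_id, year, sex, success), `ssta`
#'   (year, ssta), `truth` (the realised coefficients).
#' @export
simulate_breeding <- function(config, scores) {
  stopifnot(inherits(config, "sim_config"),
            all(c("bird_id", "score", "sex") %in% names(scores)))
  set.seed(substream(config$seed, 0L, 4L))
  yrs <- seq_len(config$years) + 2011 - config$years
  band <- rep(c("low", "medium", "high"), length.out = config$years)
  band <- sample(band)
  lo <- c(low = -0.60, medium = -0.36, high = -0.15)
  hi <- c(low = -0.36, medium = -0.15, high = 0.13)
  ssta <- stats::runif(config$years, lo[band], hi[band])
  ssta_df <- data.frame(year = yrs, ssta = ssta)
  sc <- utils::head(scores, config$n_breeding_birds)
  b <- config$fledge_beta
  score_sd <- stats::sd(sc$score)
  if (!is.finite(score_sd) || score_sd == 0) score_sd <- 1
  a <- ssta - mean(ssta)
  u_year <- stats::rnorm(config$years, 0, config$year_sd)
  u_bird <- stats::rnorm(nrow(sc), 0, config$bird_sd)
  grid <- expand.grid(bi = seq_len(nrow(sc)), yi = seq_len(config$years))
  s <- sc$score[grid$bi] / score_sd          # effect sizes are per score SD
  male <- as.numeric(sc$sex[grid$bi] == "male")
  av <- a[grid$yi]
  eta <- b[["intercept"]] + b[["ssta"]] * av + b[["sex"]] * male +
    s * (b[["score_female"]] * (1 - male) + b[["score_male"]] * male) +
    b[["score_ssta"]] * s * av + b[["sex_ssta"]] * male * av +
    b[["score_sex_ssta"]] * s * male * av +
    u_bird[grid$bi] + u_year[grid$yi]
  success <- stats::rbinom(length(eta), 1, stats::plogis(eta))
  breeding <- data.frame(bird_id = sc$bird_id[grid$bi],
                         year = yrs[grid$yi],
                         sex = sc$sex[grid$bi],
                         success = success,
                         stringsAsFactors = FALSE)
  list(breeding = breeding, ssta = ssta_df,
       truth = list(beta = b, score_sd = score_sd, ssta_mean = mean(ssta),
                    year_sd = config$year_sd, bird_sd = config$bird_sd))
}

# ---- plain-text writers ---------------------------------------------------

fmt_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Write generator outputs as the pipeline's plain-text input files
#'
#' GPS and fishing CSVs, ESRI ASCII bathymetry, behaviour, breeding and
#' SSTa CSVs, plus a ground-truth JSON for recovery checks.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @return named list of file paths, invisibly; the generated objects are
#'   returned in the `data` attribute.
#' @export
simulate_all <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gps <- simulate_gps(config)
  bathy <- simulate_bathymetry(config)
  fish <- rbind(simulate_fishing_events(config),
                simulate_attended_events(config, gps))
  beh <- simulate_behaviour(config)
  paths <- list(
    gps = file.path(out_dir, "gps_fixes.csv"),
    trip_meta = file.path(out_dir, "trip_meta.csv"),
    bathymetry = file.path(out_dir, "bathymetry.asc"),
    fishing = file.path(out_dir, "fishing_events.csv"),
    behaviour = file.path(out_dir, "behaviour.csv"),
    birds = file.path(out_dir, "birds.csv"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  g <- gps$fixes
  g$timestamp <- fmt_utc(g$timestamp)
  utils::write.csv(g, paths$gps, row.names = FALSE)
  utils::write.csv(gps$trip_meta, paths$trip_meta, row.names = FALSE)
  write_bathymetry(bathy, paths$bathymetry)
  f <- fish
  for (cc in c("set_start", "set_end", "haul_start", "haul_end"))
    f[[cc]] <- fmt_utc(f[[cc]])
  utils::write.csv(f, paths$fishing, row.names = FALSE)
  utils::write.csv(beh$observations, paths$behaviour, row.names = FALSE)
  utils::write.csv(gps$birds, paths$birds, row.names = FALSE)
  jsonlite::write_json(list(seed = config$seed,
                            icc_boldness = config$icc_boldness,
                            icc_foraging = config$icc_foraging,
                            patches = gps$patches,
                            fledge_beta = as.list(config$fledge_beta)),
                       paths$ground_truth, auto_unbox = TRUE, digits = NA)
  out <- paths
  attr(out, "data") <- list(gps = gps, bathy = bathy, fish = fish, behaviour = beh)
  invisible(out)
}
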