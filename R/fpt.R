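#' Interpolate a filtered track at a fixed along-path step
#'
#' Places points every `step_km` of cumulative along-track (great-circle)
#' distance, linearly interpolating positions and times between bracketing
#' fixes, so that first-passage time can be evaluated on an evenly spaced
#' path.
#'
#' @param trip a (speed-filtered) trip with >= 2 fixes.
#' @param step_km spacing between interpolated points, km (default 1).
#' @return data.frame with `lat`, `lon`, `time` (POSIXct) and `dist_km`
#'   (cumulative along-path distance), or NULL with a warning when the track
#'   is shorter than `2 * step_km`.
#' @export
interpolate_path <- function(trip, step_km = 1) {
  f <- trip$fixes
  if (nrow(f) < 2) stop("need >= 2 fixes to interpolate")
  n <- nrow(f)
  seg <- haversine_km(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1])
  cum <- c(0, cumsum(seg))
  total <- cum[n]
  if (total < 2 * step_km) {
    warning("track shorter than 2 interpolation steps; trip ", trip$trip_id, " skipped")
    return(NULL)
  }
  # de-duplicate zero-length segments so approx() has strictly increasing x
  keep <- c(TRUE, diff(cum) > 1e-9)
  cumk <- cum[keep]
  # tolerant endpoint rule: a path measuring 7 km up to rounding yields the
  # full 0..7 km grid; targets are clamped onto the path
  n_pts <- floor(total / step_km + 1e-9) + 1L
  targets <- pmin((seq_len(n_pts) - 1L) * step_km, total)
  tnum <- as.numeric(f$timestamp)
  data.frame(
    lat = stats::approx(cumk, f$lat[keep], xout = targets)$y,
    lon = stats::approx(cumk, f$lon[keep], xout = targets)$y,
    time = as.POSIXct(stats::approx(cumk, tnum[keep], xout = targets)$y,
                      origin = "1970-01-01", tz = "UTC"),
    dist_km = targets
  )
}

# Fraction of a straight segment travelled when distance to an external
# centre first reaches r.  d_in/d_out: distances at the inside and outside
# endpoints; len: segment length.  Exact for a planar chord (distance along
# a straight segment is the square root of a quadratic in arc length),
# which removes the bias of interpolating the crossing linearly in d.
.cross_frac <- function(d_in, d_out, len, r) {
  a <- len^2
  b <- d_out^2 - d_in^2 - a
  cc <- d_in^2 - r^2
  disc <- pmax(b^2 - 4 * a * cc, 0)
  s <- (-b + sqrt(disc)) / (2 * a)
  pmin(pmax(s, 0), 1)
}

# First exit times (hours, relative to the path's first point) from a circle
# of each radius centred at path point i, searching forward and backward.
# d: distances from point i to every path point; th: times in hours;
# cumd: cumulative along-path distance.  Returns forward and backward exit
# times per radius (NA where the path never leaves the circle).
.first_exits <- function(d, th, cumd, i, radii) {
  n <- length(d)
  fwd <- rep(NA_real_, length(radii))
  bwd <- rep(NA_real_, length(radii))
  if (i < n) {
    df <- d[(i + 1):n]
    m <- cummax(df)                       # non-decreasing -> findInterval
    pos <- findInterval(radii, m) + 1L    # first index in slice with d > r
    ok <- pos <= length(df)
    j <- i + pos[ok]                      # global index of first outside point
    prev <- j - 1L
    frac <- .cross_frac(d[prev], d[j], cumd[j] - cumd[prev], radii[ok])
    fwd[ok] <- th[prev] + frac * (th[j] - th[prev])
  }
  if (i > 1) {
    db <- d[(i - 1):1]
    m <- cummax(db)
    pos <- findInterval(radii, m) + 1L
    ok <- pos <= length(db)
    j <- i - pos[ok]                      # global index of first outside point (backward)
    nxt <- j + 1L                         # last inside point on the backward scan
    frac <- .cross_frac(d[nxt], d[j], cumd[nxt] - cumd[j], radii[ok])
    bwd[ok] <- th[nxt] - frac * (th[nxt] - th[j])
  }
  list(forward = fwd, backward = bwd)
}

#' First-passage time at one path point
#'
#' Time taken to cross a circle of radius `radius_km` centred at path point
#' `i`: the difference between the first exit forward in time and the first
#' exit backward in time.  Crossing times are refined within the crossing
#' segment by solving the planar chord geometry exactly (distance along a
#' straight segment is the square root of a quadratic in arc length).
#' Undefined (NA) when the path never leaves the circle in either
#' direction.
#'
#' @param path from [interpolate_path()].
#' @param i point index.
#' @param radius_km circle radius, km.
#' @return hours, or NA.
#' @export
first_passage_time <- function(path, i, radius_km) {
  stopifnot(i >= 1, i <= nrow(path))
  d <- haversine_km(path$lat[i], path$lon[i], path$lat, path$lon)
  th <- as.numeric(path$time - path$time[1], units = "secs") / 3600
  ex <- .first_exits(d, th, path$dist_km, i, radius_km)
  ex$forward - ex$backward
}

#' First-passage-time profile over a radius sweep
#'
#' Evaluates FPT at every path point for every radius (default 1-100 km in
#' 1-km steps).
#'
#' @param path from [interpolate_path()].
#' @param radii radius sweep, km.
#' @return object of class `fpt_profile`: list with `fpt` (points x radii
#'   matrix, hours, NA where undefined), `radii`, and the `path`.
#' @export
fpt_profile <- function(path, radii = 1:100) {
  stopifnot(!is.unsorted(radii))
  n <- nrow(path)
  th <- as.numeric(path$time - path$time[1], units = "secs") / 3600
  fpt <- matrix(NA_real_, n, length(radii))
  for (i in seq_len(n)) {
    d <- haversine_km(path$lat[i], path$lon[i], path$lat, path$lon)
    ex <- .first_exits(d, th, path$dist_km, i, radii)
    fpt[i, ] <- ex$forward - ex$backward
  }
  structure(list(fpt = fpt, radii = radii, path = path), class = "fpt_profile")
}

#' Variance of log first-passage time by radius
#'
#' The spatial scale of area-restricted search shows as a peak in the
#' variance of log(FPT) across path points.  Radii where fewer than
#' `min_points` points have defined FPT yield NA.
#'
#' @param profile an `fpt_profile`.
#' @param min_points minimum defined FPT values per radius (default 5).
#' @return numeric vector of variances (natural log scale), one per radius.
#' @export
variance_curve <- function(profile, min_points = 5) {
  apply(profile$fpt, 2, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v) < min_points) NA_real_ else stats::var(log(v))
  })
}

#' Detect peaks in the log-FPT variance curve
#'
#' Local maxima that exceed both neighbouring defined values, a relative
#' prominence floor (`prominence` times the curve maximum) and an absolute
#' variance floor.  The absolute floor separates genuine area-restricted
#' search (log-FPT variance near or above 1 when a track holds a patch)
#' from the residual wiggle of a pure commuting track (variance around
#' 0.001): peaks below it are sampling noise, not a search scale.  Ties
#' break toward the smaller radius; at most `max_peaks` peaks are returned
#' in order of descending variance.
#'
#' @param s variance curve from [variance_curve()].
#' @param radii radii matching `s`.
#' @param prominence minimum height as a fraction of max(s) (default 0.1).
#' @param min_variance absolute minimum log-FPT variance for a peak to
#'   count (default 0.05).
#' @param max_peaks maximum number of peaks returned (default 2).
#' @return data.frame with `radius_km` and `variance`; zero rows when no
#'   peak qualifies.
#' @export
detect_peaks <- function(s, radii = seq_along(s), prominence = 0.1,
                         min_variance = 0.05, max_peaks = 2) {
  ok <- which(!is.na(s))
  if (length(ok) < 3) return(data.frame(radius_km = numeric(0), variance = numeric(0)))
  sv <- s[ok]
  floor_s <- max(prominence * max(sv), min_variance)
  # collapse plateaus of equal value to their first (smallest-radius) index
  run <- cumsum(c(1, abs(diff(sv)) > 0))
  firsts <- which(!duplicated(run))
  rv <- sv[firsts]
  peaks <- integer(0)
  if (length(rv) >= 3) {
    for (k in 2:(length(rv) - 1)) {
      if (rv[k] > rv[k - 1] && rv[k] > rv[k + 1] && rv[k] >= floor_s)
        peaks <- c(peaks, ok[firsts[k]])
    }
  }
  if (!length(peaks)) return(data.frame(radius_km = numeric(0), variance = numeric(0)))
  ordp <- order(-s[peaks], radii[peaks])
  peaks <- peaks[ordp][seq_len(min(max_peaks, length(peaks)))]
  data.frame(radius_km = radii[peaks], variance = s[peaks])
}

#' Threshold separating area-restricted search from transit FPT values
#'
#' Two-class Otsu criterion on log(FPT) at the peak radius: the split point
#' maximising between-class variance, returned on the FPT (hours) scale.
#'
#' @param fpt_values defined FPT values (hours) at the peak radius.
#' @param min_values minimum sample size (default 10); fewer values is an
#'   error (zone extraction should be skipped for the trip).
#' @return threshold in hours.
#' @export
fpt_threshold <- function(fpt_values, min_values = 10) {
  v <- fpt_values[!is.na(fpt_values) & fpt_values > 0]
  if (length(v) < min_values)
    stop("fewer than ", min_values, " defined FPT values; cannot set threshold")
  x <- sort(log(v))
  n <- length(x)
  # candidate splits between consecutive distinct order statistics
  cs <- cumsum(x)
  k <- seq_len(n - 1)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  between <- (k / n) * (1 - k / n) * (m1 - m2)^2
  distinct <- x[k] < x[k + 1]
  between[!distinct] <- -Inf
  kk <- which.max(between)
  exp((x[kk] + x[kk + 1]) / 2)
}

#' Extract area-restricted-search zones along a path
#'
#' Contiguous runs of path points whose FPT at the peak radius exceeds the
#' threshold form candidate zones; zones whose centres lie within
#' `min_sep_km` of each other are merged (members pooled, centre recomputed)
#' until all pairwise centre distances exceed `min_sep_km`.
#'
#' @param profile an `fpt_profile`.
#' @param radius_km the peak radius (must be in the profile sweep).
#' @param threshold_h FPT threshold in hours.
#' @param min_sep_km minimum centre separation, km (default 10).
#' @param trip_id optional label carried into the output.
#' @return data.frame with one row per zone: `trip_id`, `centre_lat`,
#'   `centre_lon`, `n_points`, `mean_fpt_h`, `first_idx`, `last_idx`.
#' @export
extract_ars_zones <- function(profile, radius_km, threshold_h,
                              min_sep_km = 10, trip_id = NA_character_) {
  ri <- match(radius_km, profile$radii)
  if (is.na(ri)) stop("radius ", radius_km, " not in profile sweep")
  v <- profile$fpt[, ri]
  above <- !is.na(v) & v > threshold_h
  if (!any(above)) {
    return(data.frame(trip_id = character(0), centre_lat = numeric(0),
                      centre_lon = numeric(0), n_points = integer(0),
                      mean_fpt_h = numeric(0), first_idx = integer(0),
                      last_idx = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  zones <- lapply(which(r$values), function(j) starts[j]:ends[j])
  repeat {
    if (length(zones) < 2) break
    cen <- vapply(zones, function(m)
      c(mean(profile$path$lat[m]), mean(profile$path$lon[m])), numeric(2))
    merged <- FALSE
    for (a in seq_len(length(zones) - 1)) {
      db <- haversine_km(cen[1, a], cen[2, a],
                         cen[1, (a + 1):length(zones)], cen[2, (a + 1):length(zones)])
      b <- which(db <= min_sep_km)
      if (length(b)) {
        b <- a + b[1]
        zones[[a]] <- sort(unique(c(zones[[a]], zones[[b]])))
        zones[[b]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  out <- do.call(rbind, lapply(zones, function(m) {
    data.frame(trip_id = trip_id,
               centre_lat = mean(profile$path$lat[m]),
               centre_lon = mean(profile$path$lon[m]),
               n_points = length(m),
               mean_fpt_h = mean(v[m]),
               first_idx = m[1], last_idx = m[length(m)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Full FPT/ARS analysis for one trip
#'
#' Convenience wrapper: speed filter, 1-km interpolation, FPT profile over
#' the radius sweep, variance-peak detection, Otsu threshold at the
#' best (largest-variance) recoverable peak, and zone extraction.
#'
#' @param trip a segmented trip.
#' @param speed_threshold_kmh on-water filter, km/h.
#' @param step_km interpolation step, km.
#' @param radii radius sweep, km.
#' @param min_sep_km zone merge distance, km.
#' @return list with `trip_id`, `path`, `profile`, `variance`, `peaks`,
#'   `peak_radius_km`, `threshold_h`, `zones` (possibly zero-row), and
#'   `skipped` flag with `reason` when the trip cannot be analysed.
#' @export
analyse_trip_fpt <- function(trip, speed_threshold_kmh = 10, step_km = 1,
                             radii = 1:100, min_sep_km = 10) {
  skip <- function(reason) list(trip_id = trip$trip_id, skipped = TRUE, reason = reason,
                                zones = extract_ars_zones_empty(trip$trip_id))
  ft <- filter_on_water(trip, speed_threshold_kmh)
  if (!isTRUE(ft$usable_fpt)) return(skip("too few fixes after speed filter"))
  path <- withCallingHandlers(interpolate_path(ft, step_km),
                              warning = function(w) invokeRestart("muffleWarning"))
  if (is.null(path)) return(skip("track shorter than two interpolation steps"))
  prof <- fpt_profile(path, radii)
  s <- variance_curve(prof)
  pk <- detect_peaks(s, radii)
  if (!nrow(pk)) return(c(skip("no variance peak"),
                          list(path = path, profile = prof, variance = s)))
  for (p in seq_len(nrow(pk))) {
    rstar <- pk$radius_km[p]
    vals <- prof$fpt[, match(rstar, radii)]
    vals <- vals[!is.na(vals)]
    if (length(vals) >= 10) {
      thr <- fpt_threshold(vals)
      zones <- extract_ars_zones(prof, rstar, thr, min_sep_km, trip$trip_id)
      return(list(trip_id = trip$trip_id, skipped = FALSE, path = path,
                  profile = prof, variance = s, peaks = pk,
                  peak_radius_km = rstar, threshold_h = thr, zones = zones))
    }
  }
  c(skip("too few defined FPT values at every peak radius"),
    list(path = path, profile = prof, variance = s, peaks = pk))
}

extract_ars_zones_empty <- function(trip_id) {
  data.frame(trip_id = character(0), centre_lat = numeric(0),
             centre_lon = numeric(0), n_points = integer(0),
             mean_fpt_h = numeric(0), first_idx = integer(0),
             last_idx = integer(0))
}
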