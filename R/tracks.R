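#' Read a GPS fix table from CSV
#'
#' Expects columns `bird_id`, `timestamp` (ISO 8601 UTC), `lat`, `lon`
#' (signed decimal degrees, south/west negative).  A `trip_id` column, if
#' present, is carried through but never used for segmentation.  Fixes are
#' sorted in time within bird; duplicated timestamps within a bird are
#' collapsed to the first occurrence with a warning.
#'
#' @param path CSV file path.
#' @return data.frame of fixes sorted by bird then time.
#' @export
read_gps_csv <- function(path) {
  if (!file.exists(path)) stop("GPS file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "timestamp", "lat", "lon")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("GPS file missing column(s): ", paste(miss, collapse = ", "))
  t1 <- as.POSIXct(strptime(d$timestamp, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  t2 <- as.POSIXct(strptime(d$timestamp, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  t <- .POSIXct(ifelse(is.na(t1), as.numeric(t2), as.numeric(t1)), tz = "UTC")
  bad <- which(is.na(t))
  if (length(bad)) stop("Unparseable timestamp at data row(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (any(d$lat < -90 | d$lat > 90 | d$lon <= -180 | d$lon > 180))
    stop("Coordinates out of range in ", path)
  d$timestamp <- t
  d <- d[order(d$bird_id, d$timestamp), , drop = FALSE]
  dup <- duplicated(d[c("bird_id", "timestamp")])
  if (any(dup)) {
    warning(sum(dup), " duplicated bird/timestamp row(s) collapsed to first occurrence")
    d <- d[!dup, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Segment per-bird fixes into foraging trips using a colony buffer
#'
#' Maximal runs of consecutive fixes further than `buffer_km` from the colony
#' become candidate trips; runs with fewer than `min_fixes` fixes are
#' discarded as GPS jitter.  A trip is `complete` when it is flanked on both
#' sides by fixes inside the buffer (the bird was seen leaving and returning).
#'
#' @param fixes data.frame from [read_gps_csv()].
#' @param colony c(lat, lon) of the colony.
#' @param buffer_km colony exclusion radius, km (default 2).
#' @param min_fixes minimum fixes per trip (default 5).
#' @return list of trips; each a list with `trip_id`, `bird_id`, `fixes`
#'   (data.frame with `dist_col_km` added), `complete`, and `phase`
#'   (`NA` until assigned).
#' @export
segment_trips <- function(fixes, colony, buffer_km = 2, min_fixes = 5) {
  stopifnot(buffer_km > 0, min_fixes >= 2)
  trips <- list()
  for (bird in unique(fixes$bird_id)) {
    fb <- fixes[fixes$bird_id == bird, , drop = FALSE]
    fb$dist_col_km <- haversine_km(fb$lat, fb$lon, colony[[1]], colony[[2]])
    out <- fb$dist_col_km > buffer_km
    r <- rle(out)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- 0L
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < min_fixes) next
      k <- k + 1L
      seg <- fb[starts[j]:ends[j], , drop = FALSE]
      rownames(seg) <- NULL
      trips[[length(trips) + 1L]] <- list(
        trip_id = if (!is.null(seg$trip_id) && length(unique(seg$trip_id)) == 1)
          seg$trip_id[1] else paste0(bird, "_t", k),
        bird_id = bird,
        fixes = seg,
        complete = starts[j] > 1 && ends[j] < nrow(fb),
        phase = NA_character_
      )
    }
  }
  trips
}

#' Per-fix ground speed in km/h
#'
#' Speed at fix i is the haversine distance from fix i-1 divided by the time
#' difference; the first fix inherits the second fix's speed.
#'
#' @param trip a trip from [segment_trips()].
#' @return numeric vector, km/h, one per fix.
#' @export
compute_speeds <- function(trip) {
  f <- trip$fixes
  if (nrow(f) < 2) stop("need >= 2 fixes to compute speeds")
  n <- nrow(f)
  dt_h <- as.numeric(difftime(f$timestamp[-1], f$timestamp[-n], units = "hours"))
  if (any(dt_h <= 0)) stop("non-increasing timestamps within trip ", trip$trip_id)
  d <- haversine_km(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1])
  sp <- d / dt_h
  c(sp[1], sp)
}

#' Remove on-water fixes (slow speeds) before path analysis
#'
#' Fixes slower than `threshold_kmh` are taken as birds sitting on the water
#' (drift produces spurious sinuosity) and removed.  Returns a new trip; the
#' input is not modified.
#'
#' @param trip a trip.
#' @param threshold_kmh speed threshold, km/h (default 10).
#' @return a trip with slow fixes removed and `usable_fpt` flag (FALSE when
#'   fewer than 2 fixes survive).
#' @export
filter_on_water <- function(trip, threshold_kmh = 10) {
  sp <- compute_speeds(trip)
  keep <- sp >= threshold_kmh
  out <- trip
  out$fixes <- trip$fixes[keep, , drop = FALSE]
  rownames(out$fixes) <- NULL
  out$usable_fpt <- nrow(out$fixes) >= 2
  out
}

#' Trip-level foraging-effort metrics
#'
#' Four standard indices of foraging effort: trip duration (h), foraging
#' range (maximum distance from the colony, km), maximum latitude reached in
#' a northerly direction (max signed latitude, degrees) and in a southerly
#' direction (absolute value of the minimum signed latitude).
#'
#' @param trip a trip.
#' @param colony c(lat, lon).
#' @return one-row data.frame: `trip_id`, `bird_id`, `duration_h`,
#'   `max_range_km`, `max_lat_north`, `max_lat_south`.
#' @export
trip_metrics <- function(trip, colony) {
  f <- trip$fixes
  dur <- as.numeric(difftime(max(f$timestamp), min(f$timestamp), units = "hours"))
  if (dur <= 0) stop("non-positive trip duration for ", trip$trip_id)
  d <- haversine_km(f$lat, f$lon, colony[[1]], colony[[2]])
  data.frame(
    trip_id = trip$trip_id,
    bird_id = trip$bird_id,
    duration_h = dur,
    max_range_km = max(d),
    max_lat_north = max(f$lat),
    max_lat_south = abs(min(f$lat)),
    stringsAsFactors = FALSE
  )
}

#' Keep trips of one breeding phase
#'
#' Trips recorded on late-incubating birds are much longer than
#' chick-brooding trips and are excluded from the foraging-personality
#' analysis for consistency.
#'
#' @param trips list of trips with `phase` set (see [assign_phase()]).
#' @param phase phase to retain, `"brooding"` (default) or `"incubation"`.
#' @param strict error when phase labels are missing (default TRUE);
#'   otherwise trips with missing phase are retained with a warning.
#' @return filtered list of trips.
#' @export
filter_phase <- function(trips, phase = "brooding", strict = TRUE) {
  if (!phase %in% c("brooding", "incubation"))
    stop("unknown phase label: ", phase)
  ph <- vapply(trips, function(tr) tr$phase %||% NA_character_, character(1))
  if (anyNA(ph)) {
    if (strict) stop("trips without phase labels present; see assign_phase()")
    warning("trips without phase labels retained")
    return(trips[is.na(ph) | ph == phase])
  }
  trips[ph == phase]
}

#' Attach phase labels to segmented trips from a trip metadata table
#'
#' @param trips list of trips.
#' @param meta data.frame with columns `trip_id` and `phase`.
#' @return trips with `phase` filled where known.
#' @export
assign_phase <- function(trips, meta) {
  stopifnot(all(c("trip_id", "phase") %in% names(meta)))
  lapply(trips, function(tr) {
    i <- match(tr$trip_id, meta$trip_id)
    if (!is.na(i)) tr$phase <- meta$phase[i]
    tr
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
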