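#' Read an ESRI ASCII bathymetry grid
#'
#' Depths are metres, positive downward.  Rows in the file run north to
#' south, as in the ESRI ASCII convention.
#'
#' @param path .asc file.
#' @return object of class `bathy_grid`: list with `ncols`, `nrows`,
#'   `xllcorner`, `yllcorner`, `cellsize`, `nodata`, and `depth` matrix
#'   (rows north to south), NA at nodata cells.
#' @export
read_bathymetry <- function(path) {
  if (!file.exists(path)) stop("bathymetry file not found: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ESRI ASCII header line: ", ln)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("ESRI ASCII header missing: ",
                                       paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(path, skip = 6, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("grid dimension mismatch: expected ", hdr$ncols * hdr$nrows,
         " values, got ", length(vals))
  depth <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  depth[depth == nodata] <- NA_real_
  structure(list(ncols = hdr$ncols, nrows = hdr$nrows,
                 xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
                 cellsize = hdr$cellsize, nodata = nodata, depth = depth),
            class = "bathy_grid")
}

#' Write a bathymetry grid as ESRI ASCII
#'
#' @param grid a `bathy_grid`.
#' @param path output .asc path.
#' @return `path`, invisibly.
#' @export
write_bathymetry <- function(grid, path) {
  hdr <- c(
    paste("ncols", grid$ncols), paste("nrows", grid$nrows),
    paste("xllcorner", format(grid$xllcorner, digits = 12)),
    paste("yllcorner", format(grid$yllcorner, digits = 12)),
    paste("cellsize", format(grid$cellsize, digits = 12)),
    paste("NODATA_value", grid$nodata)
  )
  m <- grid$depth
  m[is.na(m)] <- grid$nodata
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Nearest-cell depth lookup
#'
#' Nearest-cell rule (no interpolation: bilinear smoothing across the shelf
#' break would manufacture intermediate depths that exist nowhere).  Ties at
#' cell boundaries break toward the lower row/column index.
#'
#' @param grid a `bathy_grid`.
#' @param lat,lon query point(s), decimal degrees.
#' @return depth(s) in metres; NA at nodata cells.
#' @export
depth_at <- function(grid, lat, lon) {
  col <- floor((lon - grid$xllcorner) / grid$cellsize) + 1L
  # cell boundary (exact multiple of cellsize) -> lower column index
  on_edge <- abs((lon - grid$xllcorner) / grid$cellsize -
                   round((lon - grid$xllcorner) / grid$cellsize)) < 1e-9
  col[on_edge] <- round((lon[on_edge] - grid$xllcorner) / grid$cellsize)
  col[on_edge & col == 0] <- 1L
  row_from_bottom <- floor((lat - grid$yllcorner) / grid$cellsize) + 1L
  on_edge <- abs((lat - grid$yllcorner) / grid$cellsize -
                   round((lat - grid$yllcorner) / grid$cellsize)) < 1e-9
  row_from_bottom[on_edge] <- round((lat[on_edge] - grid$yllcorner) / grid$cellsize)
  row_from_bottom[on_edge & row_from_bottom == 0] <- 1L
  if (any(col < 1 | col > grid$ncols | row_from_bottom < 1 | row_from_bottom > grid$nrows)) {
    bad <- which(col < 1 | col > grid$ncols | row_from_bottom < 1 | row_from_bottom > grid$nrows)[1]
    stop(sprintf("point (%.4f, %.4f) outside bathymetry grid bounds", lat[bad], lon[bad]))
  }
  row <- grid$nrows - row_from_bottom + 1L  # matrix rows run north -> south
  grid$depth[cbind(row, col)]
}

#' Classify depth into marine habitat
#'
#' Shelf: depth < 200 m.  Shelf edge: 200 m <= depth <= 2000 m.  Oceanic:
#' depth > 2000 m.  The boundary depths 200 and 2000 m belong to the shelf
#' edge (the "between" is read as a closed interval); the bounds are
#' configurable.
#'
#' @param depth metres, positive downward; NA gives NA.
#' @param shelf_max,edge_max class boundaries (default 200 and 2000 m).
#' @return factor with ordered levels shelf < shelf_edge < oceanic.
#' @export
classify_habitat <- function(depth, shelf_max = 200, edge_max = 2000) {
  out <- rep(NA_character_, length(depth))
  out[!is.na(depth) & depth < shelf_max] <- "shelf"
  out[!is.na(depth) & depth >= shelf_max & depth <= edge_max] <- "shelf_edge"
  out[!is.na(depth) & depth > edge_max] <- "oceanic"
  factor(out, levels = c("shelf", "shelf_edge", "oceanic"), ordered = TRUE)
}

#' Read a longline fishing-event table from CSV
#'
#' Columns: `line_id`, `set_start`, `set_end`, `haul_start`, `haul_end`
#' (ISO 8601 UTC), `set_lat`, `set_lon`, `haul_lat`, `haul_lon`.
#'
#' @param path CSV path.
#' @return validated data.frame with POSIXct times.
#' @export
read_fishing_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "set_start", "set_end", "haul_start", "haul_end",
            "set_lat", "set_lon", "haul_lat", "haul_lon")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("fishing file missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("set_start", "set_end", "haul_start", "haul_end"))
    d[[cc]] <- as.POSIXct(d[[cc]], tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (nrow(d) && any(!(d$set_start < d$set_end & d$set_end <= d$haul_start &
                       d$haul_start < d$haul_end)))
    stop("fishing events violate set_start < set_end <= haul_start < haul_end")
  d
}

#' Build discarding zones from fishing events
#'
#' Offal discarding starts when hauling ends and the vessel begins to move;
#' a 19-km spatial buffer (the distance a longliner can steam in the hour
#' over which discarding normally takes place) and a +1 h temporal buffer
#' around the final hauling point define the zone.
#'
#' @param events data.frame from [read_fishing_csv()].
#' @param radius_km spatial buffer, km (default 19).
#' @param window_h temporal buffer after haul end, hours (default 1).
#' @return data.frame: `line_id`, `centre_lat`, `centre_lon`,
#'   `window_start`, `window_end`, `radius_km`.
#' @export
build_discarding_zones <- function(events, radius_km = 19, window_h = 1) {
  stopifnot(radius_km > 0, window_h > 0)
  if (!nrow(events)) {
    return(data.frame(line_id = character(0), centre_lat = numeric(0),
                      centre_lon = numeric(0),
                      window_start = as.POSIXct(character(0), tz = "UTC"),
                      window_end = as.POSIXct(character(0), tz = "UTC"),
                      radius_km = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(
    line_id = events$line_id,
    centre_lat = events$haul_lat,
    centre_lon = events$haul_lon,
    window_start = events$haul_end,
    window_end = events$haul_end + window_h * 3600,
    radius_km = radius_km,
    stringsAsFactors = FALSE
  )
}

#' Does a GPS fix overlap any discarding zone?
#'
#' TRUE iff some zone has the fix within its radius and its (closed) time
#' window.
#'
#' @param fix_lat,fix_lon,fix_time fix coordinates and POSIXct time
#'   (vectorised over fixes).
#' @param zones from [build_discarding_zones()].
#' @return logical vector, one per fix.
#' @export
fix_overlap <- function(fix_lat, fix_lon, fix_time, zones) {
  n <- length(fix_lat)
  if (!nrow(zones)) return(rep(FALSE, n))
  out <- rep(FALSE, n)
  tf <- as.numeric(fix_time)
  for (z in seq_len(nrow(zones))) {
    in_window <- tf >= as.numeric(zones$window_start[z]) &
      tf <= as.numeric(zones$window_end[z])
    if (!any(in_window)) next
    iw <- which(in_window & !out)
    if (!length(iw)) next
    d <- haversine_km(fix_lat[iw], fix_lon[iw],
                      zones$centre_lat[z], zones$centre_lon[z])
    out[iw[d <= zones$radius_km[z]]] <- TRUE
  }
  out
}

#' Trip-level fisheries-overlap summary
#'
#' @param trip a trip.
#' @param zones discarding zones.
#' @return one-row data.frame: `trip_id`, `bird_id`, `any_overlap`,
#'   `prop_fixes` (overlapping fixes / total fixes) and `hours_at_vessels`
#'   (proportion times trip duration).
#' @export
trip_overlap_summary <- function(trip, zones) {
  f <- trip$fixes
  ov <- fix_overlap(f$lat, f$lon, f$timestamp, zones)
  dur <- as.numeric(difftime(max(f$timestamp), min(f$timestamp), units = "hours"))
  prop <- mean(ov)
  data.frame(trip_id = trip$trip_id, bird_id = trip$bird_id,
             any_overlap = any(ov), prop_fixes = prop,
             hours_at_vessels = prop * dur, stringsAsFactors = FALSE)
}

#' Percentage bookkeeping for fisheries overlap
#'
#' Trip-level and bird-level overlap percentages from counts: the share of
#' trips that overlapped a discarding zone at least once, and the share of
#' birds that did so on at least one trip.
#'
#' @param n_trips,n_overlap_trips total and overlapping trip counts.
#' @param n_birds,n_overlap_birds total and overlapping bird counts.
#' @return list with `pct_trips` and `pct_birds` (0-100, rounded to the
#'   nearest integer as conventionally reported) and the raw proportions.
#' @export
overlap_bookkeeping <- function(n_trips, n_overlap_trips, n_birds, n_overlap_birds) {
  stopifnot(n_overlap_trips <= n_trips, n_overlap_birds <= n_birds)
  list(pct_trips = round(100 * n_overlap_trips / n_trips),
       pct_birds = round(100 * n_overlap_birds / n_birds),
       prop_trips = n_overlap_trips / n_trips,
       prop_birds = n_overlap_birds / n_birds)
}
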