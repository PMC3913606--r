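# Shared fixtures and independent oracles, built in code.

COLONY <- c(lat = -48.4, lon = 68.4)
KM_PER_DEG <- 6371 * pi / 180

# a trip whose fixes run due east along a parallel at constant speed
straight_trip <- function(lat = 0, total_km = 10, step_km = 2, speed_kmh = 60,
                          t0 = as.POSIXct("2011-12-25 00:00:00", tz = "UTC")) {
  d <- seq(0, total_km, by = step_km)
  lon <- d / (KM_PER_DEG * cos(lat * pi / 180))
  tt <- t0 + d / speed_kmh * 3600
  list(trip_id = "straight", bird_id = "bX",
       fixes = data.frame(bird_id = "bX", trip_id = "straight",
                          timestamp = tt, lat = lat, lon = lon,
                          stringsAsFactors = FALSE))
}

# trip from local east/north offsets (km) around the colony, fixed speed
trip_from_xy <- function(x_km, y_km, speed_kmh = 40,
                         t0 = as.POSIXct("2011-12-25 00:00:00", tz = "UTC")) {
  ll <- boldtrack:::local_to_lonlat(x_km, y_km, COLONY)
  seg <- c(0, sqrt(diff(x_km)^2 + diff(y_km)^2))
  tt <- t0 + cumsum(seg) / speed_kmh * 3600
  list(trip_id = "xy", bird_id = "bX",
       fixes = data.frame(bird_id = "bX", trip_id = "xy", timestamp = tt,
                          lat = ll$lat, lon = ll$lon, stringsAsFactors = FALSE))
}

# brute-force FPT oracle: resample the interpolated path at `step` km and
# scan every dense point for the first exit in each direction
fpt_brute <- function(path, i, r, step = 0.01) {
  cum <- path$dist_km
  fine <- sort(unique(c(cum, seq(0, max(cum), by = step))))
  la <- stats::approx(cum, path$lat, fine)$y
  lo <- stats::approx(cum, path$lon, fine)$y
  tt <- stats::approx(cum, as.numeric(path$time), fine)$y
  ic <- which.min(abs(fine - cum[i]))
  d <- haversine_km(la[ic], lo[ic], la, lo)
  out_f <- which(d > r & seq_along(d) > ic)
  out_b <- which(d > r & seq_along(d) < ic)
  if (!length(out_f) || !length(out_b)) return(NA_real_)
  (tt[min(out_f)] - tt[max(out_b)]) / 3600
}

# exhaustive Otsu oracle: try every split of the sorted log values
otsu_brute <- function(v) {
  x <- sort(log(v))
  n <- length(x)
  best <- -Inf; kk <- 1
  for (k in 1:(n - 1)) {
    if (x[k] == x[k + 1]) next
    m1 <- mean(x[1:k]); m2 <- mean(x[(k + 1):n])
    b <- (k / n) * (1 - k / n) * (m1 - m2)^2
    if (b > best) { best <- b; kk <- k }
  }
  exp((x[kk] + x[kk + 1]) / 2)
}

# marginal log-likelihood of a single-random-intercept logistic model by
# non-adaptive Gauss-Hermite quadrature with `n_nodes` nodes
glmm_ll_quadrature <- function(beta, sigma, y, X, group, n_nodes = 201) {
  gh <- boldtrack:::gauss_hermite(n_nodes)
  eta0 <- drop(X %*% beta)
  ll <- 0
  for (idx in split(seq_along(y), group)) {
    lk <- vapply(seq_along(gh$nodes), function(k) {
      eta <- eta0[idx] + sqrt(2) * sigma * gh$nodes[k]
      sum(stats::dbinom(y[idx], 1, stats::plogis(eta), log = TRUE))
    }, numeric(1))
    lw <- log(gh$weights / sqrt(pi)) + lk
    m <- max(lw)
    ll <- ll + m + log(sum(exp(lw - m)))
  }
  ll
}

tiny_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_birds = 8L, trips_per_bird = 3L,
             n_behaviour_birds = 24L, years = 8L, n_breeding_birds = 8L,
             n_fishing_events = 10L, ...)
}
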