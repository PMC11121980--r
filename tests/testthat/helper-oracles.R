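# Independent oracles used to cross-check the package's bespoke numerics.
# Each is implemented from a different formulation than the code under
# test and kept deliberately simple (brute force where feasible).

# ---- solar: Michalsky (1988) approximate-almanac solar position ----
# Returns the geometric solar elevation (degrees) at a UTC instant.
# Different series and structure from the NOAA closed-form used by the
# package, hence an independent check.
oracle_solar_elevation <- function(t_utc, lat, lon) {
  jd <- as.numeric(t_utc) / 86400 + 2440587.5
  delta <- jd - 2451545.0
  mnlong <- (280.460 + 0.9856474 * delta) %% 360
  mnanom <- ((357.528 + 0.9856003 * delta) %% 360) * pi / 180
  eclong <- ((mnlong + 1.915 * sin(mnanom) + 0.020 * sin(2 * mnanom)) %%
               360) * pi / 180
  oblqec <- (23.439 - 0.0000004 * delta) * pi / 180
  dec <- asin(sin(oblqec) * sin(eclong))
  ra <- atan2(cos(oblqec) * sin(eclong), cos(eclong))
  hour_ut <- (as.numeric(t_utc) %% 86400) / 3600
  gmst <- (6.697375 + 0.0657098242 * delta + hour_ut) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- lmst * 15 * pi / 180 - ra
  latr <- lat * pi / 180
  el <- asin(sin(dec) * sin(latr) + cos(dec) * cos(latr) * cos(ha))
  el * 180 / pi
}

# Sunrise/sunset (UTC POSIXct) by root-finding the elevation crossing of
# -0.833 degrees around local solar noon/midnight.
oracle_sun_events <- function(lat, lon, utc_offset, date) {
  midnight_utc <- as.POSIXct(format(as.Date(date)), tz = "UTC") -
    utc_offset * 3600
  f <- function(h) {
    oracle_solar_elevation(midnight_utc + h * 3600, lat, lon) + 0.833
  }
  # scan hourly for sign changes over the local day
  hs <- seq(0, 24, by = 0.25)
  vals <- vapply(hs, f, numeric(1))
  crossings <- which(diff(sign(vals)) != 0)
  stopifnot(length(crossings) >= 2)
  root_at <- function(i) {
    stats::uniroot(f, c(hs[i], hs[i + 1]), tol = 1e-6)$root
  }
  up <- crossings[vals[crossings] < 0][1]        # rising crossing
  down <- crossings[vals[crossings] > 0][1]      # setting crossing
  list(sunrise = midnight_utc + root_at(up) * 3600,
       sunset = midnight_utc + root_at(down) * 3600)
}

# ---- geometry: winding-number point-in-polygon ----
# Signed-angle accumulation; inside iff total winding is non-zero.
oracle_point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- ring[i, 1] - px; y1 <- ring[i, 2] - py
    x2 <- ring[j, 1] - px; y2 <- ring[j, 2] - py
    total <- total + atan2(x1 * y2 - y1 * x2, x1 * x2 + y1 * y2)
  }
  abs(total) > pi # ~2*pi when inside, ~0 outside
}

oracle_classify <- function(lat, lon, regions) {
  vapply(seq_along(lat), function(i) {
    for (nm in regions$names) {
      inside <- FALSE
      for (ring in regions$polygons[[nm]]) {
        if (oracle_point_in_polygon(lon[i], lat[i], ring)) {
          inside <- !inside # even-odd across rings (holes/parts)
        }
      }
      if (inside) return(nm)
    }
    "other"
  }, character(1))
}

# random star-shaped (hence simple) polygon around a centre
random_simple_polygon <- function(n_vertices = 8, centre = c(0, 0),
                                  r_range = c(0.5, 2)) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_range[1], r_range[2])
  cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang))
}

# ---- segmentation: exhaustive enumeration over contiguous partitions ----
oracle_partition <- function(x, k, standardize = TRUE) {
  z <- as.numeric(x)
  if (standardize && stats::sd(z) > 0) z <- (z - mean(z)) / stats::sd(z)
  n <- length(z)
  ss <- function(v) sum((v - mean(v))^2)
  best <- Inf
  best_bounds <- NULL
  unique_opt <- TRUE
  for (cmb in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bounds <- cmb
    starts <- c(1, bounds + 1)
    ends <- c(bounds, n)
    err <- sum(mapply(function(a, b) ss(z[a:b]), starts, ends))
    if (err < best - 1e-12) {
      best <- err; best_bounds <- bounds; unique_opt <- TRUE
    } else if (abs(err - best) <= 1e-12 &&
               !identical(as.integer(bounds), as.integer(best_bounds))) {
      unique_opt <- FALSE
    }
  }
  list(error = best, boundaries = best_bounds, unique = unique_opt)
}

# ---- interpolation: explicit nearest-16-corner weighted sum ----
oracle_sample <- function(grid, t, lat, lon, h) {
  locate <- function(axis, x) {
    i <- max(which(axis <= x))
    if (i == length(axis)) i <- i - 1L
    list(i = i, w = (x - axis[i]) / (axis[i + 1] - axis[i]))
  }
  lt <- locate(as.numeric(grid$times), as.numeric(t))
  lh <- locate(grid$heights_agl, h)
  lla <- locate(grid$lats, lat)
  llo <- locate(grid$lons, lon)
  corners <- expand.grid(dt = 0:1, dh = 0:1, dla = 0:1, dlo = 0:1)
  one <- function(a) {
    sum(apply(corners, 1, function(cr) {
      w <- (if (cr["dt"]) lt$w else 1 - lt$w) *
        (if (cr["dh"]) lh$w else 1 - lh$w) *
        (if (cr["dla"]) lla$w else 1 - lla$w) *
        (if (cr["dlo"]) llo$w else 1 - llo$w)
      w * a[lt$i + cr["dt"], lh$i + cr["dh"], lla$i + cr["dla"],
            llo$i + cr["dlo"]]
    }))
  }
  list(u = one(grid$u), v = one(grid$v), temperature = one(grid$temperature))
}
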