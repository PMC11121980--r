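# Gridded wind/temperature data model: construction, validation,
# quadrilinear sampling, synthetic fields, CF-style NetCDF I/O.

#' Spatio-temporal simulation domain
#'
#' Describes the box over which a wind grid is defined: a lat/lon rectangle,
#' a height range (metres above ground level) and a time range.
#'
#' @param lat,lon numeric length-2 vectors `c(min, max)` in degrees.
#' @param height numeric length-2, metres AGL, within `[0, 5000]`.
#' @param time length-2 vector of instants (coerced to UTC `POSIXct`).
#' @return an object of class `"domain"`.
#' @examples
#' domain(lat = c(18, 30), lon = c(88, 104), height = c(0, 2000),
#'        time = c("2019-04-26 00:00", "2019-04-27 12:00"))
#' @export
domain <- function(lat, lon, height = c(0, 2000),
                   time = c("2019-04-26 00:00", "2019-04-27 12:00")) {
  time <- as_utc(time)
  d <- structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                      height = as.numeric(height), time = time),
                 class = "domain")
  for (nm in c("lat", "lon", "height")) {
    v <- d[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[1] >= v[2]) {
      stop(sprintf("degenerate domain: `%s` must be c(min, max) with min < max",
                   nm), call. = FALSE)
    }
  }
  if (length(time) != 2L || time[1] >= time[2]) {
    stop("degenerate domain: time range must have start < end", call. = FALSE)
  }
  if (d$height[1] < 0 || d$height[2] > 5000) {
    stop("height range must lie within [0, 5000] m AGL", call. = FALSE)
  }
  d
}

#' @export
print.domain <- function(x, ...) {
  cat("domain:",
      sprintf("lat [%g, %g] lon [%g, %g] height [%g, %g] m AGL",
              x$lat[1], x$lat[2], x$lon[1], x$lon[2],
              x$height[1], x$height[2]), "\n",
      " time", format(x$time[1], "%Y-%m-%d %H:%M", tz = "UTC"), "to",
      format(x$time[2], "%Y-%m-%d %H:%M", tz = "UTC"), "UTC\n")
  invisible(x)
}

#' Construct a gridded wind/temperature field
#'
#' The central meteorological container: eastward (`u`) and northward (`v`)
#' wind components plus air temperature on a regular
#' time x height x lat x lon grid. Heights are metres above ground level,
#' matching the fixed flight layers of the trajectory engine; temperature is
#' degrees Celsius.
#'
#' @param times strictly increasing UTC instants (hourly spacing typical).
#' @param heights_agl strictly increasing heights, m AGL, within `[0, 5000]`.
#' @param lats,lons strictly increasing coordinates in degrees; longitudes
#'   in `[-180, 180)`.
#' @param u,v,temperature 4-D arrays with dim
#'   `c(length(times), length(heights_agl), length(lats), length(lons))`;
#'   wind in m/s, temperature in degrees C. No missing values are allowed.
#' @param grid_spacing_km nominal horizontal spacing, stored as metadata.
#' @return an object of class `"wind_grid"`.
#' @seealso [sample_field()], [make_uniform_field()], [make_monsoon_field()]
#' @export
wind_grid <- function(times, heights_agl, lats, lons, u, v, temperature,
                      grid_spacing_km = NA_real_) {
  times <- as_utc(times)
  g <- structure(list(times = times,
                      heights_agl = as.numeric(heights_agl),
                      lats = as.numeric(lats), lons = as.numeric(lons),
                      u = u, v = v, temperature = temperature,
                      grid_spacing_km = grid_spacing_km),
                 class = "wind_grid")
  validate_wind_grid(g)
}

validate_wind_grid <- function(g) {
  dims <- c(length(g$times), length(g$heights_agl), length(g$lats),
            length(g$lons))
  if (any(dims < 2L)) {
    stop("wind_grid needs >= 2 nodes along every dimension", call. = FALSE)
  }
  for (nm in c("u", "v", "temperature")) {
    a <- g[[nm]]
    if (!is.array(a) || !identical(dim(a), as.integer(dims))) {
      stop(sprintf("`%s` must be a 4-D array of dim (time, height, lat, lon) = (%s)",
                   nm, paste(dims, collapse = ", ")), call. = FALSE)
    }
    if (anyNA(a) || !all(is.finite(a))) {
      stop(sprintf("`%s` contains missing or non-finite values", nm),
           call. = FALSE)
    }
  }
  mono <- function(x) all(diff(as.numeric(x)) > 0)
  if (!mono(g$times)) stop("times must be strictly increasing", call. = FALSE)
  if (!mono(g$heights_agl)) stop("heights_agl must be strictly increasing", call. = FALSE)
  if (!mono(g$lats)) stop("lats must be strictly increasing", call. = FALSE)
  if (!mono(g$lons)) stop("lons must be strictly increasing", call. = FALSE)
  if (min(g$heights_agl) < 0 || max(g$heights_agl) > 5000) {
    stop("heights_agl must lie within [0, 5000] m", call. = FALSE)
  }
  if (min(g$lons) < -180 || max(g$lons) >= 180) {
    stop("lons must lie within [-180, 180)", call. = FALSE)
  }
  g
}

#' @export
print.wind_grid <- function(x, ...) {
  cat("wind_grid:",
      sprintf("%d times x %d heights x %d lats x %d lons",
              length(x$times), length(x$heights_agl), length(x$lats),
              length(x$lons)), "\n")
  cat(sprintf("  lat [%g, %g]  lon [%g, %g]  height [%g, %g] m AGL\n",
              min(x$lats), max(x$lats), min(x$lons), max(x$lons),
              min(x$heights_agl), max(x$heights_agl)))
  cat("  time", format(min(x$times), "%Y-%m-%d %H:%M", tz = "UTC"), "to",
      format(max(x$times), "%Y-%m-%d %H:%M", tz = "UTC"), "UTC\n")
  cat(sprintf("  u [%.2f, %.2f] m/s  v [%.2f, %.2f] m/s  T [%.1f, %.1f] C\n",
              min(x$u), max(x$u), min(x$v), max(x$v),
              min(x$temperature), max(x$temperature)))
  invisible(x)
}

grid_axes <- function(domain, resolution) {
  res <- as.list(resolution)
  need <- c("n_time", "n_height", "n_lat", "n_lon")
  missing_n <- setdiff(need, names(res))
  if (length(missing_n)) {
    stop("resolution must name ", paste(missing_n, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(res[need]) < 2)) {
    stop("resolution must yield >= 2 nodes per dimension", call. = FALSE)
  }
  list(times = as_utc(seq(domain$time[1], domain$time[2],
                          length.out = res$n_time)),
       heights = seq(domain$height[1], domain$height[2],
                     length.out = res$n_height),
       lats = seq(domain$lat[1], domain$lat[2], length.out = res$n_lat),
       lons = seq(domain$lon[1], domain$lon[2], length.out = res$n_lon))
}

#' Uniform synthetic wind field
#'
#' Every node carries the same wind vector and temperature; useful because
#' trajectory displacement through such a field has a closed form.
#'
#' @param u0,v0 wind components, m/s.
#' @param t0 air temperature, degrees C.
#' @param domain a [domain()].
#' @param resolution named list `n_time`, `n_height`, `n_lat`, `n_lon`
#'   (node counts, each >= 2).
#' @return a [wind_grid()].
#' @examples
#' g <- make_uniform_field(10, 0, 20, domain(c(20, 28), c(92, 104)))
#' sample_field(g, g$times[1] + 1800, 24, 98, 450)
#' @export
make_uniform_field <- function(u0, v0, t0,
                               domain = domain(c(18, 30), c(88, 104)),
                               resolution = list(n_time = 16, n_height = 6,
                                                 n_lat = 9, n_lon = 9)) {
  stopifnot_scalar(u0, "u0"); stopifnot_scalar(v0, "v0")
  stopifnot_scalar(t0, "t0")
  ax <- grid_axes(domain, resolution)
  dims <- c(length(ax$times), length(ax$heights), length(ax$lats),
            length(ax$lons))
  wind_grid(ax$times, ax$heights, ax$lats, ax$lons,
            u = array(u0, dims), v = array(v0, dims),
            temperature = array(t0, dims))
}

#' Idealised monsoon wind field
#'
#' Emulates the seasonal monsoon reversal that carries migrating moths:
#' in spring a warm southwesterly flow (u > 0, v > 0, toward the
#' northeast), in autumn a northeasterly flow (u < 0, v < 0, toward the
#' southwest). Temperature falls linearly with height at the supplied lapse
#' rate. A seeded smooth spatial perturbation (superposed sinusoids, bounded
#' to at most 40% of `speed`) keeps the field non-trivial without flipping
#' the sign of either component.
#'
#' @param season `"spring"` or `"autumn"`.
#' @param speed mean wind speed along each component, m/s (>= 0).
#' @param t_surface surface air temperature, degrees C.
#' @param lapse lapse rate, degrees C per 100 m.
#' @param domain,resolution as in [make_uniform_field()].
#' @param seed integer seed for the perturbation; `NULL` disables it.
#' @return a [wind_grid()].
#' @export
make_monsoon_field <- function(season = c("spring", "autumn"), speed = 5,
                               t_surface = 25, lapse = 0.65,
                               domain = domain(c(18, 30), c(88, 104)),
                               resolution = list(n_time = 16, n_height = 6,
                                                 n_lat = 9, n_lon = 9),
                               seed = NULL) {
  season <- match.arg(season)
  if (!is_scalar_number(speed) || speed < 0) {
    stop("`speed` must be a single non-negative number", call. = FALSE)
  }
  ax <- grid_axes(domain, resolution)
  dims <- c(length(ax$times), length(ax$heights), length(ax$lats),
            length(ax$lons))
  sgn <- if (season == "spring") 1 else -1
  u <- array(sgn * speed, dims)
  v <- array(sgn * speed * 0.8, dims)
  if (!is.null(seed) && speed > 0) {
    set.seed(as.integer(seed))
    ph <- runif(6, 0, 2 * pi)
    la <- array(rep(ax$lats, each = dims[1] * dims[2]), dims)
    lo <- array(rep(ax$lons, each = prod(dims[1:3])), dims)
    pert <- sin(2 * pi * la / diff(range(ax$lats)) + ph[1]) *
      cos(2 * pi * lo / diff(range(ax$lons)) + ph[2])
    # bounded perturbation: |pert| <= 1, scaled to 40% so signs never flip
    u <- u * (1 + 0.4 * pert)
    v <- v * (1 + 0.4 * sin(2 * pi * lo / diff(range(ax$lons)) + ph[3]) *
                cos(2 * pi * la / diff(range(ax$lats)) + ph[4]))
  }
  hh <- array(rep(ax$heights, each = dims[1]), dims)
  temperature <- array(t_surface, dims) - lapse * hh / 100
  wind_grid(ax$times, ax$heights, ax$lats, ax$lons, u, v, temperature)
}

#' Is a query point inside a grid's hull?
#'
#' @param grid a [wind_grid()].
#' @param t instant (UTC `POSIXct` or string).
#' @param lat,lon,h_agl query coordinates.
#' @return logical.
#' @export
in_domain <- function(grid, t, lat, lon, h_agl) {
  t <- as.numeric(as_utc(t))
  tt <- as.numeric(grid$times)
  t >= tt[1] & t <= tt[length(tt)] &
    lat >= grid$lats[1] & lat <= grid$lats[length(grid$lats)] &
    lon >= grid$lons[1] & lon <= grid$lons[length(grid$lons)] &
    h_agl >= grid$heights_agl[1] &
    h_agl <= grid$heights_agl[length(grid$heights_agl)]
}

# locate x in ascending axis: returns list(i, w) with
# value = (1-w)*axis[i] + w*axis[i+1]; assumes x inside hull
axis_locate <- function(axis, x) {
  n <- length(axis)
  i <- findInterval(unname(x), axis, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), n - 1L)
  w <- (unname(x) - axis[i]) / (axis[i + 1L] - axis[i])
  list(i = i, w = w)
}

#' Sample a wind grid at an arbitrary point
#'
#' Quadrilinear interpolation: trilinear in (height, lat, lon) and linear in
#' time, i.e. a convex combination of the 16 enclosing grid corners. Exact
#' at grid nodes.
#'
#' @inheritParams in_domain
#' @param on_outside `"error"` to reject out-of-hull queries, `"na"` to
#'   return NA values (the trajectory engine treats that as a boundary
#'   exit).
#' @return named list `u`, `v`, `temperature`.
#' @export
sample_field <- function(grid, t, lat, lon, h_agl,
                         on_outside = c("error", "na")) {
  on_outside <- match.arg(on_outside)
  if (!in_domain(grid, t, lat, lon, h_agl)) {
    if (on_outside == "error") {
      stop("query point outside the grid hull", call. = FALSE)
    }
    return(list(u = NA_real_, v = NA_real_, temperature = NA_real_))
  }
  at <- axis_locate(as.numeric(grid$times), as.numeric(as_utc(t)))
  ah <- axis_locate(grid$heights_agl, h_agl)
  ala <- axis_locate(grid$lats, lat)
  alo <- axis_locate(grid$lons, lon)
  interp1 <- function(a) {
    acc <- 0
    for (dt in 0:1) for (dh in 0:1) for (dla in 0:1) for (dlo in 0:1) {
      w <- (if (dt) at$w else 1 - at$w) * (if (dh) ah$w else 1 - ah$w) *
        (if (dla) ala$w else 1 - ala$w) * (if (dlo) alo$w else 1 - alo$w)
      if (w > 0) {
        acc <- acc + w * a[at$i + dt, ah$i + dh, ala$i + dla, alo$i + dlo]
      }
    }
    acc
  }
  list(u = interp1(grid$u), v = interp1(grid$v),
       temperature = interp1(grid$temperature))
}

#' Write a wind grid to a CF-style NetCDF file
#'
#' Dimensions `time` (hours since 1970-01-01), `height` (m AGL), `lat`,
#' `lon`; variables `u`, `v` (m s-1) and `T` (degrees C), each dimensioned
#' (lon, lat, height, time) as NetCDF stores fastest-varying first. Grid
#' spacing metadata is kept as a global attribute.
#'
#' @param grid a [wind_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wind_netcdf <- function(grid, path) {
  dim_time <- ncdf4::ncdim_def("time", "hours since 1970-01-01 00:00:00",
                               as.numeric(grid$times) / 3600,
                               unlim = FALSE)
  dim_h <- ncdf4::ncdim_def("height", "m", grid$heights_agl)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", grid$lats)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", grid$lons)
  dims <- list(dim_lon, dim_lat, dim_h, dim_time)
  var_u <- ncdf4::ncvar_def("u", "m s-1", dims, prec = "double",
                            longname = "eastward_wind")
  var_v <- ncdf4::ncvar_def("v", "m s-1", dims, prec = "double",
                            longname = "northward_wind")
  var_t <- ncdf4::ncvar_def("T", "degC", dims, prec = "double",
                            longname = "air_temperature")
  nc <- ncdf4::nc_create(path, list(var_u, var_v, var_t))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  # internal layout is (time, height, lat, lon); NetCDF wants the reverse
  flip <- function(a) aperm(a, c(4, 3, 2, 1))
  ncdf4::ncvar_put(nc, var_u, flip(grid$u))
  ncdf4::ncvar_put(nc, var_v, flip(grid$v))
  ncdf4::ncvar_put(nc, var_t, flip(grid$temperature))
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8")
  ncdf4::ncatt_put(nc, "height", "long_name", "height above ground level")
  if (is.finite(grid$grid_spacing_km)) {
    ncdf4::ncatt_put(nc, 0, "grid_spacing_km", grid$grid_spacing_km)
  }
  invisible(path)
}

# parse a CF "units since epoch" time axis to UTC POSIXct
cf_time_to_utc <- function(vals, units) {
  m <- regmatches(units, regexec(
    "^(seconds|minutes|hours|days)\\s+since\\s+([0-9]{4}-[0-9]{2}-[0-9]{2})[ T]?([0-9:]{5,8})?",
    units))[[1]]
  if (length(m) == 0) {
    stop("unsupported time units: ", units, call. = FALSE)
  }
  mult <- c(seconds = 1, minutes = 60, hours = 3600, days = 86400)[[m[2]]]
  origin <- as_utc(paste(m[3], if (nzchar(m[4])) m[4] else "00:00:00"))
  origin + vals * mult
}

#' Read a wind grid from a CF-style NetCDF file
#'
#' Accepts the layout [write_wind_netcdf()] produces, with configurable
#' variable-name aliases for externally produced files. Descending latitude
#' or longitude axes are normalised to ascending (fields re-ordered to
#' match); temperatures with a Kelvin unit attribute are converted to
#' degrees C.
#'
#' @param path NetCDF file path.
#' @param var_names named character vector mapping internal names to file
#'   variable names, default `c(u = "u", v = "v", temperature = "T")`.
#' @return a [wind_grid()].
#' @export
read_wind_netcdf <- function(path,
                             var_names = c(u = "u", v = "v",
                                           temperature = "T")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  for (nm in var_names) {
    if (!nm %in% names(nc$var)) {
      stop(sprintf("file is missing required variable `%s`", nm),
           call. = FALSE)
    }
  }
  getdim <- function(cands) {
    hit <- intersect(cands, names(nc$dim))
    if (!length(hit)) {
      stop("file lacks a dimension named one of: ",
           paste(cands, collapse = ", "), call. = FALSE)
    }
    nc$dim[[hit[1]]]
  }
  d_time <- getdim(c("time", "Time"))
  d_h <- getdim(c("height", "lev", "level", "z"))
  d_lat <- getdim(c("lat", "latitude"))
  d_lon <- getdim(c("lon", "longitude"))
  times <- cf_time_to_utc(d_time$vals, d_time$units)
  heights <- as.numeric(d_h$vals)
  lats <- as.numeric(d_lat$vals)
  lons <- as.numeric(d_lon$vals)

  getvar <- function(nm) {
    a <- ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)
    # file order (lon, lat, height, time) -> internal (time, height, lat, lon)
    aperm(a, c(4, 3, 2, 1))
  }
  u <- getvar(var_names[["u"]])
  v <- getvar(var_names[["v"]])
  temperature <- getvar(var_names[["temperature"]])
  t_units <- ncdf4::ncatt_get(nc, var_names[["temperature"]], "units")
  if (isTRUE(t_units$hasatt) && grepl("^(K|kelvin)", t_units$value,
                                      ignore.case = TRUE)) {
    temperature <- temperature - 273.15
  }

  flip_axis <- function(axis, margin) {
    if (all(diff(axis) < 0)) {
      idx <- rev(seq_along(axis))
      sel <- function(a) {
        args <- rep(list(quote(expr = )), 4)
        args[[margin]] <- idx
        do.call(`[`, c(list(a), args, list(drop = FALSE)))
      }
      u <<- sel(u); v <<- sel(v); temperature <<- sel(temperature)
      rev(axis)
    } else {
      axis
    }
  }
  lats <- flip_axis(lats, 3L)
  lons <- flip_axis(lons, 4L)
  heights <- flip_axis(heights, 2L)

  spacing <- ncdf4::ncatt_get(nc, 0, "grid_spacing_km")
  wind_grid(times, heights, lats, lons, u, v, temperature,
            grid_spacing_km = if (isTRUE(spacing$hasatt))
              as.numeric(spacing$value) else NA_real_)
}

#' Export vertical profiles sampled from a grid as CSV
#'
#' Debugging aid: samples `u`, `v`, `temperature` at one horizontal
#' position and time across a set of heights and writes one row per height.
#'
#' @inheritParams in_domain
#' @param heights heights to sample, m AGL.
#' @param path output CSV path.
#' @return the profile `data.frame`, invisibly.
#' @export
export_profile_csv <- function(grid, t, lat, lon,
                               heights = grid$heights_agl, path) {
  rows <- lapply(heights, function(h) {
    s <- sample_field(grid, t, lat, lon, h)
    data.frame(time = format(as_utc(t), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               lat = lat, lon = lon, height_agl = h,
               u = s$u, v = s$v, temperature = s$temperature)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
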