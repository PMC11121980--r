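# Lagrangian trajectory integration at fixed AGL flight layers within a
# nightly flight window. Horizontal motion equals the interpolated wind
# (downwind drift, no self-powered airspeed); a temperature threshold gates
# take-off; trajectories stop at the window end or the domain boundary.

#' Trajectory simulation parameters
#'
#' @param step time step in seconds (default 600, i.e. positions recorded
#'   every 10 minutes).
#' @param altitudes_agl flight layers in metres above ground level; one
#'   trajectory is integrated per layer. Default: 100--1000 m in 100 m
#'   steps, the band where radar shows migrating moths concentrate.
#' @param temp_threshold flight temperature threshold in degrees C (default
#'   13.1, the critical flight temperature established for the congeneric
#'   fall armyworm); below it flight is not initiated.
#' @param temp_gate `"takeoff_only"` (default) applies the threshold at the
#'   release point and instant only; `"continuous"` additionally terminates
#'   a flight the first time the sampled temperature drops below the
#'   threshold.
#' @param integrator `"euler"` (default; each step uses the wind at the
#'   step's start) or `"midpoint"` (second-order, for sensitivity checks).
#' @return an object of class `"trajectory_params"`.
#' @export
trajectory_params <- function(step = 600,
                              altitudes_agl = seq(100, 1000, by = 100),
                              temp_threshold = 13.1,
                              temp_gate = c("takeoff_only", "continuous"),
                              integrator = c("euler", "midpoint")) {
  temp_gate <- match.arg(temp_gate)
  integrator <- match.arg(integrator)
  if (!is_scalar_number(step) || step <= 0) {
    stop("`step` must be a single positive number of seconds", call. = FALSE)
  }
  if (!length(altitudes_agl) || any(altitudes_agl <= 0)) {
    stop("altitudes_agl must be positive heights (m AGL)", call. = FALSE)
  }
  if (!is.numeric(temp_threshold) || length(temp_threshold) != 1L ||
      is.na(temp_threshold)) {
    stop("`temp_threshold` must be a single number", call. = FALSE)
  }
  structure(list(step = step, altitudes_agl = sort(altitudes_agl),
                 temp_threshold = temp_threshold, temp_gate = temp_gate,
                 integrator = integrator),
            class = "trajectory_params")
}

#' Release specification for one simulated night
#'
#' @param lat,lon release point in degrees (the trap site for backward
#'   runs; any point of interest for forward runs).
#' @param date local calendar date of the night.
#' @param direction `"forward"` (predicts landing areas; integration runs
#'   from take-off to the landing deadline) or `"backward"` (infers source
#'   areas; integration runs from the landing deadline back to take-off
#'   against the wind).
#' @param window a [flight_window()] for that night.
#' @return an object of class `"release_spec"`.
#' @export
release_spec <- function(lat, lon, date, direction = c("forward", "backward"),
                         window) {
  direction <- match.arg(direction)
  stopifnot_scalar(lat, "lat"); stopifnot_scalar(lon, "lon")
  stopifnot(inherits(window, "flight_window"))
  structure(list(lat = lat, lon = lon, date = as.Date(date),
                 direction = direction, window = window),
            class = "release_spec")
}

# one integration step: wind (m/s) over dt seconds -> new (lat, lon)
advance_position <- function(lat, lon, u, v, dt) {
  lat <- unname(lat); lon <- unname(lon); u <- unname(u); v <- unname(v)
  c(lat = lat + (v * dt) / M_PER_DEG_LAT,
    lon = lon + (u * dt) / (M_PER_DEG_LON_EQ * cos(deg2rad(lat))))
}

new_trajectory <- function(release, altitude, points, termination) {
  structure(list(release = release, altitude_agl = altitude,
                 points = points, termination = termination,
                 endpoint = points[nrow(points), , drop = FALSE]),
            class = "moth_trajectory")
}

#' @export
print.moth_trajectory <- function(x, ...) {
  ep <- x$endpoint
  cat(sprintf("trajectory: %s, %s m AGL, night of %s\n",
              x$release$direction, format(x$altitude_agl),
              format(x$release$date)))
  cat(sprintf("  %d points, termination: %s\n", nrow(x$points),
              x$termination))
  cat(sprintf("  release (%.3f, %.3f) -> endpoint (%.3f, %.3f)\n",
              x$release$lat, x$release$lon, ep$lat, ep$lon))
  invisible(x)
}

#' Simulate one night of trajectories across all flight layers
#'
#' For each altitude layer: if the temperature sampled at the release point
#' and release instant is below the flight threshold, the trajectory is a
#' single point terminated `temperature_stop`. Otherwise positions advance
#' downwind by `wind x step` (forward) or retrace upwind by `-wind x step`
#' (backward, time decreasing from the landing deadline toward take-off),
#' recorded every step. A trajectory terminates `window_end` when the
#' flight window is exhausted, or `boundary_exit` the first time the next
#' proposed point would leave the grid hull (the last inside point is
#' kept). In `"continuous"` gate mode it additionally terminates
#' `temperature_stop` when the sampled temperature first drops below the
#' threshold mid-flight. Altitude is constant along a trajectory.
#'
#' @param release a [release_spec()].
#' @param grid a [wind_grid()].
#' @param params a [trajectory_params()].
#' @return a list of `"moth_trajectory"` objects (one per altitude), class
#'   `"trajectory_set"`.
#' @export
simulate_trajectories <- function(release, grid,
                                  params = trajectory_params()) {
  stopifnot(inherits(release, "release_spec"), inherits(grid, "wind_grid"),
            inherits(params, "trajectory_params"))
  w <- release$window
  t0 <- if (release$direction == "forward") w$takeoff else w$landing_deadline
  t_end <- if (release$direction == "forward") w$landing_deadline else w$takeoff
  sgn <- if (release$direction == "forward") 1 else -1
  if (!in_domain(grid, t0, release$lat, release$lon,
                 params$altitudes_agl[1])) {
    if (as.numeric(t0) < as.numeric(grid$times[1]) ||
        as.numeric(t0) > as.numeric(grid$times[length(grid$times)]) ||
        as.numeric(t_end) < as.numeric(grid$times[1]) ||
        as.numeric(t_end) > as.numeric(grid$times[length(grid$times)])) {
      stop("flight window lies outside the grid's time range", call. = FALSE)
    }
    stop("release origin lies outside the grid domain", call. = FALSE)
  }
  if (as.numeric(t_end) < as.numeric(grid$times[1]) ||
      as.numeric(t_end) > as.numeric(grid$times[length(grid$times)])) {
    stop("flight window lies outside the grid's time range", call. = FALSE)
  }

  out <- lapply(params$altitudes_agl, function(alt) {
    integrate_one(release, grid, params, alt, t0, t_end, sgn)
  })
  structure(out, class = "trajectory_set")
}

integrate_one <- function(release, grid, params, alt, t0, t_end, sgn) {
  dt <- params$step
  point_row <- function(t, lat, lon, s) {
    data.frame(time = as_utc(t), lat = lat, lon = lon, altitude_agl = alt,
               u = s$u, v = s$v, temperature = s$temperature)
  }
  s0 <- sample_field(grid, t0, release$lat, release$lon, alt)
  pts <- point_row(t0, release$lat, release$lon, s0)
  if (s0$temperature < params$temp_threshold) {
    return(new_trajectory(release, alt, pts, "temperature_stop"))
  }
  t <- t0; lat <- release$lat; lon <- release$lon; s <- s0
  termination <- "window_end"
  while (sgn * as.numeric(difftime(t_end, t, units = "secs")) >= dt) {
    t_next <- t + sgn * dt
    if (params$integrator == "euler") {
      nxt <- advance_position(lat, lon, sgn * s$u, sgn * s$v, dt)
    } else {
      half <- advance_position(lat, lon, sgn * s$u, sgn * s$v, dt / 2)
      t_half <- t + sgn * dt / 2
      if (!in_domain(grid, t_half, half["lat"], half["lon"], alt)) {
        termination <- "boundary_exit"
        break
      }
      sm <- sample_field(grid, t_half, half["lat"], half["lon"], alt)
      nxt <- advance_position(lat, lon, sgn * sm$u, sgn * sm$v, dt)
    }
    if (!in_domain(grid, t_next, nxt["lat"], nxt["lon"], alt)) {
      termination <- "boundary_exit"
      break
    }
    s <- sample_field(grid, t_next, nxt["lat"], nxt["lon"], alt)
    t <- t_next; lat <- unname(nxt["lat"]); lon <- unname(nxt["lon"])
    pts <- rbind(pts, point_row(t, lat, lon, s))
    if (params$temp_gate == "continuous" &&
        s$temperature < params$temp_threshold) {
      termination <- "temperature_stop"
      break
    }
  }
  new_trajectory(release, alt, pts, termination)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d trajectories (%s, night of %s)\n",
              length(x), x[[1]]$release$direction,
              format(x[[1]]$release$date)))
  for (tr in x) {
    cat(sprintf("  %4g m AGL: %3d points, %s\n", tr$altitude_agl,
                nrow(tr$points), tr$termination))
  }
  invisible(x)
}

#' @export
plot.trajectory_set <- function(x, ...) {
  all_pts <- do.call(rbind, lapply(x, function(tr) tr$points))
  graphics::plot(all_pts$lon, all_pts$lat, type = "n",
                 xlab = "longitude (deg E)", ylab = "latitude (deg N)", ...)
  cols <- grDevices::hcl.colors(length(x), "Zissou 1")
  for (i in seq_along(x)) {
    p <- x[[i]]$points
    graphics::lines(p$lon, p$lat, col = cols[i])
    graphics::points(p$lon[nrow(p)], p$lat[nrow(p)], pch = 16,
                     col = cols[i], cex = 0.8)
  }
  graphics::points(x[[1]]$release$lon, x[[1]]$release$lat, pch = 17)
  invisible(x)
}

#' Extract trajectory endpoints
#'
#' One row per trajectory: the latest integrated point. Forward endpoints
#' are candidate landing points; backward endpoints are candidate take-off
#' (source) points.
#'
#' @param trajectories a `"trajectory_set"`, a list of them, or a list of
#'   `"moth_trajectory"` objects.
#' @return data.frame with columns `date`, `direction`, `season`,
#'   `altitude_agl`, `time`, `lat`, `lon`, `termination`.
#' @export
trajectory_endpoints <- function(trajectories) {
  trs <- flatten_trajectories(trajectories)
  if (!length(trs)) stop("no trajectories supplied", call. = FALSE)
  rows <- lapply(trs, function(tr) {
    ep <- tr$endpoint
    data.frame(date = tr$release$date, direction = tr$release$direction,
               season = migration_season(tr$release$date),
               altitude_agl = tr$altitude_agl, time = ep$time,
               lat = ep$lat, lon = ep$lon, termination = tr$termination,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract every recorded trajectory point
#'
#' Alternative to [trajectory_endpoints()] when attribution should use all
#' 10-minute positions rather than only the final one.
#'
#' @inheritParams trajectory_endpoints
#' @return data.frame with one row per recorded point.
#' @export
trajectory_points <- function(trajectories) {
  trs <- flatten_trajectories(trajectories)
  if (!length(trs)) stop("no trajectories supplied", call. = FALSE)
  rows <- lapply(trs, function(tr) {
    p <- tr$points
    data.frame(date = tr$release$date, direction = tr$release$direction,
               season = migration_season(tr$release$date),
               altitude_agl = tr$altitude_agl, time = p$time,
               lat = p$lat, lon = p$lon, termination = tr$termination,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

flatten_trajectories <- function(x) {
  if (inherits(x, "moth_trajectory")) return(list(x))
  out <- list()
  for (el in x) {
    if (inherits(el, "moth_trajectory")) {
      out <- c(out, list(el))
    } else {
      out <- c(out, flatten_trajectories(el))
    }
  }
  out
}

#' Simulate a batch of release nights
#'
#' Deterministically enumerates (date, direction) combinations in order and
#' integrates each; per-run failures are caught and reported without
#' aborting the batch.
#'
#' @param site a [site()] giving the release point and clock offset.
#' @param dates local dates of the nights to simulate.
#' @param directions character vector, subset of
#'   `c("forward", "backward")`; each is run for every date.
#' @param grid a [wind_grid()].
#' @param params a [trajectory_params()].
#' @return list with elements `trajectories` (list of `"trajectory_set"`,
#'   ordered by date then direction) and `failures` (data.frame of date,
#'   direction, message).
#' @export
batch_simulate <- function(site, dates, directions = c("forward", "backward"),
                           grid, params = trajectory_params()) {
  stopifnot(inherits(site, "site"))
  directions <- match.arg(directions, c("forward", "backward"),
                          several.ok = TRUE)
  dates <- sort(as.Date(dates))
  runs <- expand.grid(direction = directions, date = dates,
                      stringsAsFactors = FALSE)[, c("date", "direction")]
  runs <- runs[order(runs$date, runs$direction), ]
  sets <- list()
  fails <- list()
  for (i in seq_len(nrow(runs))) {
    d <- runs$date[i]; dir <- runs$direction[i]
    res <- tryCatch({
      w <- flight_window(site, d)
      rel <- release_spec(site$lat, site$lon, d, dir, w)
      simulate_trajectories(rel, grid, params)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        date = d, direction = dir, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      sets[[length(sets) + 1L]] <- res
    }
  }
  list(trajectories = sets,
       failures = if (length(fails)) do.call(rbind, fails) else
         data.frame(date = as.Date(character()), direction = character(),
                    message = character()))
}

#' Write trajectories to CSV (one row per point)
#'
#' @inheritParams trajectory_endpoints
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  trs <- flatten_trajectories(trajectories)
  rows <- lapply(seq_along(trs), function(i) {
    tr <- trs[[i]]
    cbind(run = i, date = format(tr$release$date),
          direction = tr$release$direction,
          altitude_agl = tr$altitude_agl,
          tr$points[, c("time", "lat", "lon", "u", "v", "temperature")],
          termination = tr$termination)
  })
  out <- do.call(rbind, rows)
  out$time <- format(out$time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write endpoints as GeoJSON points
#'
#' @param endpoints data.frame from [trajectory_endpoints()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_endpoints_geojson <- function(endpoints, path) {
  features <- lapply(seq_len(nrow(endpoints)), function(i) {
    e <- endpoints[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(e$lon, e$lat)),
         properties = list(date = format(e$date), direction = e$direction,
                           season = e$season,
                           altitude_agl = e$altitude_agl,
                           termination = e$termination))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
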