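# Solar ephemeris (NOAA closed-form algorithm, zenith 90.833 deg) and the
# nightly flight window it induces: migrating moths take off about 20 min
# after sunset and land about 10 min before the next sunrise.

#' Define a monitoring site
#'
#' @param lat latitude, degrees north; `|lat| <= 66.5` (no polar day/night
#'   handling).
#' @param lon longitude, degrees east.
#' @param utc_offset fixed clock offset from UTC in hours, in `[-12, 14]`.
#' @param name optional label.
#' @return an object of class `"site"`.
#' @examples
#' ruili_site()
#' @export
site <- function(lat, lon, utc_offset = 0, name = "") {
  stopifnot_scalar(lat, "lat"); stopifnot_scalar(lon, "lon")
  stopifnot_scalar(utc_offset, "utc_offset")
  if (abs(lat) > 66.5) {
    stop("unsupported latitude: |lat| must be <= 66.5 (no polar handling)",
         call. = FALSE)
  }
  if (utc_offset < -12 || utc_offset > 14) {
    stop("utc_offset must lie in [-12, 14] hours", call. = FALSE)
  }
  structure(list(lat = lat, lon = lon, utc_offset = utc_offset,
                 name = name), class = "site")
}

#' @export
print.site <- function(x, ...) {
  cat(sprintf("site%s: %.4f N, %.4f E (UTC%+g)\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              x$lat, x$lon, x$utc_offset))
  invisible(x)
}

#' The Ruili searchlight-trap site
#'
#' The monitoring site on the China--Myanmar border used throughout the
#' worked examples: 23.98 N, 97.83 E, clock UTC+8. (The published
#' coordinate string uses minute values above 59 and is therefore read as
#' decimal degrees.)
#'
#' @return a [site()].
#' @export
ruili_site <- function() site(23.98, 97.83, utc_offset = 8, name = "Ruili")

# NOAA solar position pieces; all angles in degrees unless noted.
# jc = Julian centuries since J2000 at the instant of interest.
noaa_solar <- function(jc) {
  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  C <- sin(deg2rad(M)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * M)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * M)) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- rad2deg(asin(sin(deg2rad(eps)) * sin(deg2rad(app_long))))
  y <- tan(deg2rad(eps / 2))^2
  eqtime <- 4 * rad2deg(
    y * sin(2 * deg2rad(L0)) - 2 * e * sin(deg2rad(M)) +
      4 * e * y * sin(deg2rad(M)) * cos(2 * deg2rad(L0)) -
      0.5 * y^2 * sin(4 * deg2rad(L0)) -
      1.25 * e^2 * sin(2 * deg2rad(M)))
  list(decl = decl, eqtime = eqtime) # eqtime in minutes
}

julian_centuries <- function(t_utc) {
  (as.numeric(t_utc) / 86400 + 2440587.5 - 2451545) / 36525
}

# one sunrise/sunset pass: returns local clock minutes from local midnight,
# or NA when the sun never crosses the zenith circle (polar cases are
# rejected upstream)
sun_pass <- function(lat, lon, utc_offset, date, zenith, jc) {
  sol <- noaa_solar(jc)
  cos_ha <- cos(deg2rad(zenith)) /
    (cos(deg2rad(lat)) * cos(deg2rad(sol$decl))) -
    tan(deg2rad(lat)) * tan(deg2rad(sol$decl))
  if (abs(cos_ha) > 1) return(c(NA_real_, NA_real_))
  ha <- rad2deg(acos(cos_ha))
  noon <- 720 - 4 * lon - sol$eqtime + utc_offset * 60
  c(rise = noon - 4 * ha, set = noon + 4 * ha)
}

#' Sunrise and sunset for a site and date
#'
#' NOAA closed-form solar position with zenith 90.833 degrees (standard
#' atmospheric refraction plus the solar radius) at sea level. Two
#' refinement passes re-evaluate the solar declination and equation of time
#' at the estimated event instants, giving agreement with a numerical
#' ephemeris well inside two minutes at non-polar latitudes.
#'
#' @param site a [site()].
#' @param date the local calendar date (`Date` or string).
#' @param zenith solar zenith angle defining the event, degrees.
#' @return named list with UTC `POSIXct` elements `sunrise` and `sunset`
#'   (that local date's events) plus `sunrise_local`/`sunset_local` clock
#'   strings.
#' @examples
#' sun_events(ruili_site(), "2019-04-26")
#' @export
sun_events <- function(site, date, zenith = 90.833) {
  stopifnot(inherits(site, "site"))
  date <- tryCatch(as.Date(date), error = function(e) NA)
  if (is.na(date)) stop("invalid date", call. = FALSE)
  midnight_utc <- as_utc(format(date)) - site$utc_offset * 3600
  # first pass at local noon, then refine at the event estimates
  est <- sun_pass(site$lat, site$lon, site$utc_offset, date, zenith,
                  julian_centuries(midnight_utc + 12 * 3600))
  if (anyNA(est)) {
    stop("sun never crosses the horizon circle on this date at this latitude",
         call. = FALSE)
  }
  for (i in 1:2) {
    # est holds local clock minutes from local midnight; midnight_utc is
    # already the UTC instant of that local midnight
    rise_utc <- midnight_utc + est[1] * 60
    set_utc <- midnight_utc + est[2] * 60
    r <- sun_pass(site$lat, site$lon, site$utc_offset, date, zenith,
                  julian_centuries(rise_utc))
    s <- sun_pass(site$lat, site$lon, site$utc_offset, date, zenith,
                  julian_centuries(set_utc))
    est <- c(r[1], s[2])
  }
  sunrise <- midnight_utc + est[1] * 60
  sunset <- midnight_utc + est[2] * 60
  list(sunrise = unname(sunrise), sunset = unname(sunset),
       sunrise_local = format_local(sunrise, site$utc_offset),
       sunset_local = format_local(sunset, site$utc_offset))
}

#' Nightly flight window
#'
#' The interval over which nocturnal migration is simulated: take-off at
#' `sunset(date) + takeoff_offset` and a landing deadline at
#' `sunrise(date + 1) - landing_offset`. The default offsets (20 min after
#' sunset, 10 min before sunrise) are the peak take-off and landing times
#' observed for migrating noctuid moths.
#'
#' @inheritParams sun_events
#' @param takeoff_offset minutes after sunset at which flight begins.
#' @param landing_offset minutes before the next sunrise at which flight
#'   must end.
#' @return an object of class `"flight_window"` with UTC `POSIXct` fields
#'   `takeoff` and `landing_deadline`.
#' @examples
#' flight_window(ruili_site(), "2019-04-26")
#' @export
flight_window <- function(site, date, takeoff_offset = 20,
                          landing_offset = 10) {
  date <- as.Date(date)
  ev_today <- sun_events(site, date)
  ev_next <- sun_events(site, date + 1)
  takeoff <- ev_today$sunset + takeoff_offset * 60
  landing <- ev_next$sunrise - landing_offset * 60
  if (takeoff >= landing) {
    stop("degenerate flight window: take-off not before landing deadline",
         call. = FALSE)
  }
  structure(list(date = date, takeoff = takeoff,
                 landing_deadline = landing,
                 sunset = ev_today$sunset, sunrise_next = ev_next$sunrise,
                 takeoff_offset = takeoff_offset,
                 landing_offset = landing_offset,
                 utc_offset = site$utc_offset),
            class = "flight_window")
}

#' @export
print.flight_window <- function(x, ...) {
  cat(sprintf("flight window for night of %s:\n", format(x$date)))
  cat(sprintf("  take-off %s  (sunset %s + %g min)\n",
              format_local(x$takeoff, x$utc_offset),
              format_local(x$sunset, x$utc_offset), x$takeoff_offset))
  cat(sprintf("  landing deadline %s next day  (sunrise %s - %g min)\n",
              format_local(x$landing_deadline, x$utc_offset),
              format_local(x$sunrise_next, x$utc_offset), x$landing_offset))
  cat(sprintf("  duration %.1f h\n", window_duration(x)))
  invisible(x)
}

#' Duration of a flight window in hours
#' @param window a [flight_window()].
#' @return numeric hours.
#' @export
window_duration <- function(window) {
  as.numeric(difftime(window$landing_deadline, window$takeoff,
                      units = "hours"))
}

#' Tabulate flight windows over a span of dates
#'
#' @param site a [site()].
#' @param dates vector of local dates.
#' @param path optional CSV output path.
#' @inheritParams flight_window
#' @return data.frame with one row per date (local clock times).
#' @export
flight_window_table <- function(site, dates, takeoff_offset = 20,
                                landing_offset = 10, path = NULL) {
  rows <- lapply(as.Date(dates), function(d) {
    w <- flight_window(site, d, takeoff_offset, landing_offset)
    data.frame(date = format(d),
               sunset = format_local(w$sunset, site$utc_offset),
               sunrise_next = format_local(w$sunrise_next, site$utc_offset),
               takeoff = format_local(w$takeoff, site$utc_offset),
               landing_deadline = format_local(w$landing_deadline,
                                               site$utc_offset),
               duration_h = round(window_duration(w), 2))
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
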