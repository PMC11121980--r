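# Fixtures built in code: synthetic windows, grids and region sets.

# a flight window of exact duration (hours), detached from the ephemeris,
# for closed-form trajectory arithmetic
fixed_window <- function(date = "2019-04-26", start_utc = "2019-04-26 12:00:00",
                         duration_h = 12) {
  takeoff <- as.POSIXct(start_utc, tz = "UTC")
  structure(list(date = as.Date(date), takeoff = takeoff,
                 landing_deadline = takeoff + duration_h * 3600,
                 sunset = takeoff - 20 * 60,
                 sunrise_next = takeoff + duration_h * 3600 + 10 * 60,
                 takeoff_offset = 20, landing_offset = 10, utc_offset = 8),
            class = "flight_window")
}

# a compact uniform grid around the study area covering one night
test_grid <- function(u = 10, v = 0, temp = 20,
                      lat = c(18, 30), lon = c(88, 106),
                      time = c("2019-04-26 00:00", "2019-04-28 00:00")) {
  make_uniform_field(u, v, temp,
                     domain(lat, lon, c(0, 2000), time),
                     resolution = list(n_time = 9, n_height = 5,
                                       n_lat = 7, n_lon = 7))
}

# two disjoint unit squares, handy for classifier edge cases
two_squares <- function() {
  region_set(list(
    A = list(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))),
    B = list(rbind(c(2, 0), c(3, 0), c(3, 1), c(2, 1)))))
}

# the published seasonal attribution percentages (four regions x four
# direction/season cells), used as a round-trip fixture
published_attribution <- function() {
  m <- matrix(c(5.9, 54.3, 6.1, 33.6,
                48.1, 51.9, 0, 0,
                94.0, 6.0, 0, 0,
                22.0, 73.3, 2.0, 2.7),
              nrow = 4,
              dimnames = list(c("China", "Myanmar", "India", "Bangladesh"),
                              c("backward/spring", "backward/autumn",
                                "forward/spring", "forward/autumn")))
  m
}

# the published monthly mean female catches (per-month mean over five
# years) and mean female percentages
published_monthly_means <- c(50.0, 83.6, 515.0, 2570.8, 1380.8, 370.8,
                             287.8, 170.2, 242.6, 344.2, 210.2, 70.0)
published_monthly_pct <- c(21.5, 25.8, 38.7, 60.4, 42.3, 28.9, 29.1,
                           25.7, 25.8, 28.3, 27.0, 21.2)

# nightly series whose monthly female totals average (over 5 years) to the
# published monthly means exactly: total*5 is an integer for one-decimal
# means, distributed as floor + remainder across years
reconstructed_series <- function() {
  years <- 2019:2023
  rows <- list()
  for (m in 1:12) {
    tot5 <- round(published_monthly_means[m] * 5)
    base <- tot5 %/% 5
    rem <- tot5 %% 5
    fem_y <- rep(base, 5) + c(rep(1, rem), rep(0, 5 - rem))
    # males sized so the pooled monthly percentage is near the published one
    for (i in seq_along(years)) {
      f <- fem_y[i]
      males <- max(0, round(f / (published_monthly_pct[m] / 100)) - f)
      rows[[length(rows) + 1L]] <- data.frame(
        date = as.Date(sprintf("%d-%02d-15", years[i], m)),
        females = f, males = males)
    }
  }
  catch_series(do.call(rbind, rows))
}
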