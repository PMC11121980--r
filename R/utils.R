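# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

# metres per degree at the working scale (<= ~700 km); great-circle
# refinement is unnecessary at this resolution
M_PER_DEG_LAT <- 110574
M_PER_DEG_LON_EQ <- 111320

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# round half-up to `digits` decimals (base round() is half-to-even;
# presentation tables in this field round half-up)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# POSIXct in UTC from "YYYY-MM-DD HH:MM[:SS]" or Date-like input
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(format(x), tz = "UTC"))
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

# format a UTC instant as local clock time at a fixed UTC offset (hours)
format_local <- function(t_utc, utc_offset, fmt = "%H:%M") {
  format(t_utc + utc_offset * 3600, fmt, tz = "UTC")
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar <- function(x, what) {
  if (!is_scalar_number(x)) {
    stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
  }
  invisible(x)
}

# month -> migration season, following the study's period segmentation:
# April-May spring, October-December autumn, remaining months transition
#' Migration season of a date
#'
#' Maps calendar months onto the migration periods used throughout the
#' package: April--May is the spring migration period, October--December the
#' autumn migration period, and every other month a transition period.
#'
#' @param date a `Date` (or something coercible to one).
#' @return character vector with values `"spring"`, `"autumn"` or
#'   `"transition"`.
#' @examples
#' migration_season(as.Date(c("2019-04-26", "2019-11-02", "2020-07-01")))
#' @export
migration_season <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  out <- rep("transition", length(m))
  out[m %in% c(4L, 5L)] <- "spring"
  out[m %in% c(10L, 11L, 12L)] <- "autumn"
  out
}

#' Peak migration nights used for trajectory simulation
#'
#' The ten peak trap-catch nights (one spring and one autumn night per year,
#' 2019--2023) that the trajectory workflow simulates by default, with the
#' number of moths trapped on each night.
#'
#' @return a `data.frame` with columns `date`, `season` and `catch`.
#' @examples
#' peak_migration_days()
#' @export
peak_migration_days <- function() {
  out <- data.frame(
    date = as.Date(c("2019-04-26", "2020-05-16", "2021-05-17", "2022-04-27",
                     "2023-04-15", "2019-11-02", "2020-11-15", "2021-10-11",
                     "2022-10-28", "2023-11-11")),
    catch = c(2288L, 596L, 304L, 275L, 725L, 61L, 46L, 95L, 307L, 234L),
    stringsAsFactors = FALSE
  )
  out$season <- migration_season(out$date)
  out[order(out$date), c("date", "season", "catch")]
}
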