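# Synthetic nightly trap-catch and dissection data with the statistical
# structure the phenology analysis assumes: overdispersed nightly counts
# with two seasonal peaks, month-varying sex ratio, period-dependent
# ovarian maturity, and a nightly dissection cap.

#' Configuration for the synthetic trap-catch generator
#'
#' Defaults emulate the seasonal structure observed at the study site: a
#' dominant spring migration peak in late April, a smaller autumn peak in
#' early November, monthly female fractions following the observed
#' sex-ratio seasonality (highest in April, the only month where females
#' outnumber males), and higher ovarian maturity and mating rates in the
#' spring period than in autumn (matured fractions 0.923 vs 0.742, mated
#' 0.833 vs 0.629).
#'
#' @param years calendar years to simulate (one record per night).
#' @param baseline baseline nightly catch intensity (moths/night, > 0).
#' @param peaks list of seasonal components, each
#'   `list(center, width, amplitude)`: a Gaussian bump on day-of-year
#'   (wrapping at year end) added to the baseline intensity.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed; `Inf` recovers Poisson).
#' @param female_fraction length-12 vector of monthly female fractions in
#'   (0, 1).
#' @param ovary_probs named list of length-5 multinomial probability
#'   vectors over ovary levels 1--5, one per period label.
#' @param mated_rate named numeric vector of mated fractions per period.
#' @param mating_lambda rate of the zero-truncated Poisson for the mating
#'   count of mated females.
#' @param dissection_cap maximum females dissected per night (default 20,
#'   or all females when fewer are caught).
#' @return an object of class `"trap_sim_config"`.
#' @export
trap_sim_config <- function(
    years = 2019:2023,
    baseline = 8,
    peaks = list(spring = list(center = 118, width = 16, amplitude = 120),
                 autumn = list(center = 310, width = 22, amplitude = 35)),
    dispersion = 3,
    female_fraction = c(0.215, 0.258, 0.387, 0.604, 0.423, 0.289, 0.291,
                        0.257, 0.258, 0.283, 0.270, 0.212),
    ovary_probs = list(
      spring = c(0.030, 0.047, 0.200, 0.470, 0.253),
      autumn = c(0.110, 0.148, 0.252, 0.340, 0.150),
      transition = c(0.060, 0.090, 0.250, 0.420, 0.180)),
    mated_rate = c(spring = 0.833, autumn = 0.629, transition = 0.800),
    mating_lambda = 1.6,
    dissection_cap = 20) {
  if (!is_scalar_number(baseline) || baseline <= 0) {
    stop("`baseline` must be a positive number", call. = FALSE)
  }
  for (p in peaks) {
    if (!all(c("center", "width", "amplitude") %in% names(p)) ||
        p$width <= 0 || p$amplitude < 0) {
      stop("each peak needs center, width > 0, amplitude >= 0",
           call. = FALSE)
    }
  }
  if (length(female_fraction) != 12 ||
      any(female_fraction <= 0 | female_fraction >= 1)) {
    stop("`female_fraction` must be 12 values in (0, 1)", call. = FALSE)
  }
  for (nm in names(ovary_probs)) {
    pr <- ovary_probs[[nm]]
    if (length(pr) != 5 || any(pr < 0) ||
        abs(sum(pr) - 1) > 1e-8) {
      stop(sprintf("ovary_probs$%s must be 5 probabilities summing to 1",
                   nm), call. = FALSE)
    }
  }
  if (any(mated_rate <= 0 | mated_rate > 1)) {
    stop("`mated_rate` values must lie in (0, 1]", call. = FALSE)
  }
  if (!is_scalar_number(dispersion) || dispersion <= 0) {
    stop("`dispersion` must be positive (Inf for Poisson)", call. = FALSE)
  }
  structure(list(years = years, baseline = baseline, peaks = peaks,
                 dispersion = dispersion,
                 female_fraction = female_fraction,
                 ovary_probs = ovary_probs, mated_rate = mated_rate,
                 mating_lambda = mating_lambda,
                 dissection_cap = dissection_cap),
            class = "trap_sim_config")
}

# seasonal mean intensity on a day-of-year grid, with wraparound
seasonal_mean <- function(doy, config, year_length = 365) {
  mu <- rep(config$baseline, length(doy))
  for (p in config$peaks) {
    delta <- abs(doy - p$center)
    delta <- pmin(delta, year_length - delta) # circular distance
    mu <- mu + p$amplitude * exp(-0.5 * (delta / p$width)^2)
  }
  mu
}

rtrunc_pois <- function(n, lambda) {
  # zero-truncated Poisson by inversion of the conditional CDF
  u <- stats::runif(n)
  stats::qpois(stats::ppois(0, lambda) + u * (1 - stats::ppois(0, lambda)),
               lambda)
}

#' Generate a synthetic trap-catch series
#'
#' Nightly totals are negative-binomial with mean `baseline + sum of
#' seasonal Gaussian bumps`; females are binomial in the total with the
#' month's female fraction; up to `dissection_cap` females per night
#' receive an ovary level (period-specific multinomial) and a mating count
#' (zero with probability `1 - mated_rate`, else zero-truncated Poisson).
#'
#' @param config a [trap_sim_config()].
#' @param seed integer seed; recorded in the output's attributes.
#' @return a [catch_series()] with both nightly counts and dissection
#'   records; attributes `seed` and `config`.
#' @export
generate_catches <- function(config = trap_sim_config(), seed = 1) {
  stopifnot(inherits(config, "trap_sim_config"))
  set.seed(as.integer(seed))
  dates <- seq(as.Date(sprintf("%d-01-01", min(config$years))),
               as.Date(sprintf("%d-12-31", max(config$years))), by = "day")
  dates <- dates[as.integer(format(dates, "%Y")) %in% config$years]
  doy <- as.integer(format(dates, "%j"))
  mo <- as.integer(format(dates, "%m"))
  mu <- seasonal_mean(pmin(doy, 365), config)
  total <- if (is.finite(config$dispersion)) {
    stats::rnbinom(length(dates), size = config$dispersion, mu = mu)
  } else {
    stats::rpois(length(dates), mu)
  }
  females <- stats::rbinom(length(dates), total,
                           config$female_fraction[mo])
  nightly <- data.frame(date = dates, females = females,
                        males = total - females, total = total)
  period <- migration_season(dates)
  n_diss <- pmin(config$dissection_cap, females)
  idx <- rep.int(seq_along(dates), n_diss)
  per <- period[idx]
  lvl <- integer(length(idx))
  for (p in unique(per)) {
    sel <- per == p
    pr <- config$ovary_probs[[p]]
    if (is.null(pr)) {
      stop("no ovary_probs entry for period: ", p, call. = FALSE)
    }
    lvl[sel] <- sample.int(5, sum(sel), replace = TRUE, prob = pr)
  }
  mated <- stats::rbinom(length(idx), 1,
                         unname(config$mated_rate[per]))
  mc <- integer(length(idx))
  if (any(mated == 1)) {
    mc[mated == 1] <- rtrunc_pois(sum(mated), config$mating_lambda)
  }
  dissections <- data.frame(date = dates[idx], ovary_level = lvl,
                            mating_count = mc)
  out <- catch_series(nightly, dissections)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "config") <- config
  out
}

#' Generate a labelled endpoint cloud matching target percentages
#'
#' Samples `n` points per column inside the named region polygons so that
#' [attribute_endpoints()] reproduces the supplied percentage table
#' exactly (counts are `pct * n / 100`, which must be whole numbers —
#' satisfied for one-decimal percentages whenever `n` is a multiple of
#' 1000). Used to round-trip published attribution tables through the
#' classifier.
#'
#' @param percentages matrix or data.frame: rows = region names, columns =
#'   group labels of the form `"direction/season"` (e.g.
#'   `"backward/spring"`); each column sums to ~100.
#' @param n points per column.
#' @param regions a [region_set()] containing every row's region.
#' @param seed integer seed.
#' @return data.frame with columns `lat`, `lon`, `region_true`,
#'   `direction`, `season`.
#' @export
generate_endpoint_cloud <- function(percentages, n = 1000, regions,
                                    seed = 1) {
  stopifnot(inherits(regions, "region_set"))
  pct <- as.matrix(percentages)
  if (is.null(rownames(pct)) || is.null(colnames(pct))) {
    stop("percentages need region rownames and group colnames",
         call. = FALSE)
  }
  unknown <- setdiff(rownames(pct), regions$names)
  if (length(unknown)) {
    stop("no polygon for region(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad <- abs(colSums(pct) - 100) > 0.2
  if (any(bad)) {
    stop("column(s) do not sum to ~100: ",
         paste(colnames(pct)[bad], collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- list()
  for (col in colnames(pct)) {
    counts <- stats::setNames(pct[, col] * n / 100, rownames(pct))
    if (any(abs(counts - round(counts)) > 1e-6)) {
      stop(sprintf("column %s: percentages x n/100 must be whole counts",
                   col), call. = FALSE)
    }
    counts <- round(counts)
    if (sum(counts) > n) {
      stop(sprintf("column %s: counts exceed n", col), call. = FALSE)
    }
    # a column summing to slightly under 100 (printed rounding) is padded
    # with points outside every region so the group total is exactly n
    counts <- c(counts, other = n - sum(counts))
    ds <- strsplit(col, "/", fixed = TRUE)[[1]]
    for (rg in names(counts)) {
      m <- counts[[rg]]
      if (m == 0) next
      pts <- if (rg == "other") {
        sample_outside_regions(regions, m)
      } else {
        sample_in_region(regions, rg, m)
      }
      out[[length(out) + 1L]] <- data.frame(
        lat = pts[, 2], lon = pts[, 1], region_true = rg,
        direction = ds[1], season = if (length(ds) > 1) ds[2] else "all",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# uniform rejection sampling inside a region's polygons (bounding-box
# proposals; immediate acceptance for rectangular fixtures)
sample_in_region <- function(regions, name, m) {
  rings <- regions$polygons[[name]]
  allv <- do.call(rbind, rings)
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  got <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(got) < m) {
    tries <- tries + 1
    if (tries > 1000) {
      stop("rejection sampling failed for region: ", name, call. = FALSE)
    }
    k <- max(2 * (m - nrow(got)), 16)
    # stay strictly inside the hull so boundary tie-breaks never bite
    px <- stats::runif(k, xr[1] + 1e-6 * diff(xr), xr[2] - 1e-6 * diff(xr))
    py <- stats::runif(k, yr[1] + 1e-6 * diff(yr), yr[2] - 1e-6 * diff(yr))
    keep <- vapply(seq_len(k), function(i) {
      point_in_rings(px[i], py[i], rings)
    }, logical(1))
    got <- rbind(got, cbind(px[keep], py[keep]))
  }
  got[seq_len(m), , drop = FALSE]
}

# points outside every region: proposals in an expanded bounding box of
# all polygons, rejected while inside any region
sample_outside_regions <- function(regions, m) {
  allv <- do.call(rbind, unlist(regions$polygons, recursive = FALSE))
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  pad_x <- 0.2 * diff(xr); pad_y <- 0.2 * diff(yr)
  got <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(got) < m) {
    tries <- tries + 1
    if (tries > 1000) {
      stop("could not sample points outside all regions", call. = FALSE)
    }
    k <- max(2 * (m - nrow(got)), 16)
    px <- stats::runif(k, xr[1] - pad_x, xr[2] + pad_x)
    py <- stats::runif(k, yr[1] - pad_y, yr[2] + pad_y)
    keep <- vapply(seq_len(k), function(i) {
      for (nm in regions$names) {
        if (point_in_rings(px[i], py[i], regions$polygons[[nm]])) {
          return(FALSE)
        }
      }
      TRUE
    }, logical(1))
    got <- rbind(got, cbind(px[keep], py[keep]))
  }
  got[seq_len(m), , drop = FALSE]
}
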