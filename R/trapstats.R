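# Light-trap phenology statistics: monthly catch summaries, the 1:1
# sex-ratio chi-square, Fisher optimal partitioning of ordered samples
# (migration-period segmentation), and ovarian development summaries.

#' Construct a trap-catch series
#'
#' @param nightly data.frame with columns `date`, `females`, `males`
#'   (non-negative integer counts per trap-night); a `total` column is
#'   derived (or validated when present).
#' @param dissections optional data.frame of per-female dissection records
#'   with columns `date`, `ovary_level` (integer 1--5) and `mating_count`
#'   (non-negative integer spermatophore count).
#' @return an object of class `"catch_series"`.
#' @export
catch_series <- function(nightly, dissections = NULL) {
  stopifnot(is.data.frame(nightly))
  need <- setdiff(c("date", "females", "males"), names(nightly))
  if (length(need)) {
    stop("nightly records lack columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  nightly$date <- as.Date(nightly$date)
  for (col in c("females", "males")) {
    v <- nightly[[col]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      stop(sprintf("`%s` must be non-negative integer counts", col),
           call. = FALSE)
    }
  }
  if ("total" %in% names(nightly)) {
    if (any(nightly$total != nightly$females + nightly$males)) {
      stop("total must equal females + males", call. = FALSE)
    }
  } else {
    nightly$total <- nightly$females + nightly$males
  }
  if (!is.null(dissections)) {
    stopifnot(is.data.frame(dissections))
    needd <- setdiff(c("date", "ovary_level", "mating_count"),
                     names(dissections))
    if (length(needd)) {
      stop("dissection records lack columns: ",
           paste(needd, collapse = ", "), call. = FALSE)
    }
    dissections$date <- as.Date(dissections$date)
    if (!all(dissections$ovary_level %in% 1:5)) {
      stop("ovary_level must be in 1..5", call. = FALSE)
    }
    if (any(dissections$mating_count < 0) ||
        any(dissections$mating_count != round(dissections$mating_count))) {
      stop("mating_count must be non-negative integers", call. = FALSE)
    }
  }
  structure(list(nightly = nightly[order(nightly$date), ],
                 dissections = dissections),
            class = "catch_series")
}

#' @export
print.catch_series <- function(x, ...) {
  n <- x$nightly
  cat(sprintf("catch_series: %d trap-nights, %s to %s\n", nrow(n),
              format(min(n$date)), format(max(n$date))))
  cat(sprintf("  total moths %d (females %d, males %d)\n", sum(n$total),
              sum(n$females), sum(n$males)))
  if (!is.null(x$dissections)) {
    cat(sprintf("  %d dissected females\n", nrow(x$dissections)))
  }
  invisible(x)
}

#' Read / write trap-catch CSV files
#'
#' @param nightly_path CSV of nightly counts (`date,females,males`).
#' @param dissections_path optional CSV of dissection records
#'   (`date,ovary_level,mating_count`).
#' @return a [catch_series()].
#' @export
read_catches_csv <- function(nightly_path, dissections_path = NULL) {
  nightly <- utils::read.csv(nightly_path, stringsAsFactors = FALSE)
  diss <- if (!is.null(dissections_path)) {
    utils::read.csv(dissections_path, stringsAsFactors = FALSE)
  }
  catch_series(nightly, diss)
}

#' @rdname read_catches_csv
#' @param series a [catch_series()].
#' @param path output CSV path for the nightly table; when
#'   `dissections_path` is given the dissection table is written there too.
#' @export
write_catches_csv <- function(series, path, dissections_path = NULL) {
  stopifnot(inherits(series, "catch_series"))
  n <- series$nightly
  n$date <- format(n$date)
  utils::write.csv(n, path, row.names = FALSE)
  if (!is.null(dissections_path) && !is.null(series$dissections)) {
    d <- series$dissections
    d$date <- format(d$date)
    utils::write.csv(d, dissections_path, row.names = FALSE)
  }
  invisible(path)
}

#' Monthly female-catch summary
#'
#' For each calendar month: the mean (over years) of the monthly female
#' total, its standard error, the mean female percentage, and the 1:1
#' sex-ratio chi-square of the pooled monthly counts. The grand total is
#' the sum of the monthly means.
#'
#' @param series a [catch_series()].
#' @return class `"monthly_summary"`: data.frame with one row per observed
#'   month (`month`, `mean_females`, `se_females`, `mean_pct_female`,
#'   `se_pct_female`, `chi_square`, `p_value`, `n_years`) plus attribute
#'   `total` (sum of monthly means).
#' @export
monthly_summary <- function(series) {
  stopifnot(inherits(series, "catch_series"))
  n <- series$nightly
  if (!nrow(n)) stop("empty catch series", call. = FALSE)
  yr <- as.integer(format(n$date, "%Y"))
  mo <- as.integer(format(n$date, "%m"))
  # per (year, month) totals, then mean/SE across years within month
  fem_ym <- tapply(n$females, list(yr, mo), sum)
  mal_ym <- tapply(n$males, list(yr, mo), sum)
  months <- sort(unique(mo))
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  rows <- lapply(months, function(m) {
    f <- fem_ym[, as.character(m)]
    ml <- mal_ym[, as.character(m)]
    keep <- !is.na(f)
    f <- f[keep]; ml <- ml[keep]
    pct <- 100 * f / (f + ml)
    test <- sex_ratio_chisq(sum(f), sum(ml))
    data.frame(month = m, mean_females = mean(f), se_females = se(f),
               mean_pct_female = mean(pct), se_pct_female = se(pct),
               chi_square = test$chi_square, p_value = test$p_value,
               n_years = length(f))
  })
  out <- do.call(rbind, rows)
  structure(out, total = sum(out$mean_females), class = c("monthly_summary",
                                                          "data.frame"))
}

#' @export
print.monthly_summary <- function(x, ...) {
  df <- as.data.frame(x)
  df$mean_females <- round_half_up(df$mean_females, 1)
  df$se_females <- round_half_up(df$se_females, 1)
  df$mean_pct_female <- round_half_up(df$mean_pct_female, 1)
  df$se_pct_female <- round_half_up(df$se_pct_female, 1)
  df$chi_square <- round_half_up(df$chi_square, 3)
  df$p_value <- signif(df$p_value, 3)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("grand total of monthly means: %.1f females\n",
              attr(x, "total")))
  invisible(x)
}

#' Sex-ratio chi-square against a 1:1 expectation
#'
#' Two-cell Pearson chi-square with expected counts `(F + M) / 2` in each
#' cell, which reduces to `(F - M)^2 / (F + M)` on 1 degree of freedom.
#' Yates continuity correction is off by default and available as a flag.
#'
#' @param females,males observed counts (not both zero).
#' @param correct apply the Yates continuity correction.
#' @return class `"sex_ratio_test"`: list with `females`, `males`,
#'   `chi_square`, `p_value`.
#' @examples
#' sex_ratio_chisq(60, 40) # chi-square 4, p ~ 0.0455
#' @export
sex_ratio_chisq <- function(females, males, correct = FALSE) {
  stopifnot_scalar(females, "females"); stopifnot_scalar(males, "males")
  if (females < 0 || males < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  n <- females + males
  if (n == 0) stop("at least one moth is required", call. = FALSE)
  d <- abs(females - males)
  if (correct) d <- max(0, d - 1)
  chi <- d^2 / n
  structure(list(females = females, males = males, chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 correct = correct),
            class = "sex_ratio_test")
}

#' @export
print.sex_ratio_test <- function(x, ...) {
  cat(sprintf("1:1 sex-ratio chi-square: F = %g, M = %g\n", x$females,
              x$males))
  cat(sprintf("  X-squared = %.3f, df = 1, p = %.4g%s\n", x$chi_square,
              x$p_value, if (x$correct) " (Yates-corrected)" else ""))
  invisible(x)
}

# within-class sum of squared deviations of x[i..j], via prefix sums
block_ss_fun <- function(x) {
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  function(i, j) {
    n <- j - i + 1
    s <- s1[j + 1] - s1[i]
    max(0, (s2[j + 1] - s2[i]) - s^2 / n)
  }
}

#' Fisher optimal partitioning of an ordered series
#'
#' Exact dynamic-programming segmentation of an ordered sample into `k`
#' contiguous classes minimising the total within-class sum of squared
#' deviations — the classical change-point method used to divide a
#' seasonal catch series into migration periods. The optimum is global
#' over all contiguous partitions. Ties are broken toward the leftmost
#' boundaries (each class boundary as small as possible, scanning
#' candidate cuts in ascending order with strict improvement).
#'
#' @param x numeric series in its natural order; names (e.g. month labels)
#'   are carried through to the class summaries.
#' @param k number of classes, `2 <= k <= length(x)`.
#' @param standardize z-score the series first (default). A constant
#'   series cannot be standardized; it is segmented as-is with a warning
#'   and zero error.
#' @return class `"segmentation"`: list with `k`, `boundaries` (indices of
#'   the last element of classes 1..k-1), `classes` (list of index
#'   vectors), `class_means` (on the working scale), `error_function`
#'   (minimal total within-class SS), `standardized` flag.
#' @seealso [segmentation_scan()]
#' @export
fisher_partition <- function(x, k, standardize = TRUE) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (!is_scalar_number(k) || k != round(k) || k < 2 || k > n) {
    stop("`k` must be an integer in [2, length(x)]", call. = FALSE)
  }
  k <- as.integer(k)
  labels <- names(x)
  z <- as.numeric(x)
  standardized <- FALSE
  if (standardize) {
    s <- stats::sd(z)
    if (is.na(s) || s == 0) {
      warning("constant series: standardization skipped", call. = FALSE)
    } else {
      z <- (z - mean(z)) / s
      standardized <- TRUE
    }
  }
  ss <- block_ss_fun(z)
  # F[m, j]: minimal error splitting z[1..j] into m classes
  Fm <- matrix(Inf, k, n)
  cut <- matrix(NA_integer_, k, n)
  for (j in 1:n) Fm[1, j] <- ss(1, j)
  for (m in 2:k) {
    for (j in m:n) {
      best <- Inf; best_i <- NA_integer_
      for (i in m:j) { # class m is z[i..j]
        val <- Fm[m - 1, i - 1] + ss(i, j)
        if (val < best - 1e-12) { # strict improvement => leftmost cuts
          best <- val; best_i <- i
        }
      }
      Fm[m, j] <- best
      cut[m, j] <- best_i
    }
  }
  # recover boundaries
  bounds <- integer(k - 1)
  j <- n
  for (m in k:2) {
    i <- cut[m, j]
    bounds[m - 1] <- i - 1L
    j <- i - 1L
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  classes <- Map(seq, starts, ends)
  structure(list(k = k, boundaries = bounds, classes = classes,
                 class_means = vapply(classes, function(ix) mean(z[ix]),
                                      numeric(1)),
                 error_function = max(0, Fm[k, n]),
                 standardized = standardized, labels = labels,
                 x = as.numeric(x)),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("optimal partition into k = %d classes (error function %.4f%s)\n",
              x$k, x$error_function,
              if (x$standardized) ", standardized" else ""))
  for (i in seq_along(x$classes)) {
    ix <- x$classes[[i]]
    lab <- if (!is.null(x$labels)) {
      paste0(x$labels[ix[1]], if (length(ix) > 1)
        paste0("-", x$labels[ix[length(ix)]]) else "")
    } else {
      paste0(ix[1], if (length(ix) > 1) paste0("-", ix[length(ix)]) else "")
    }
    cat(sprintf("  class %d: %s (mean %.3f)\n", i, lab, x$class_means[i]))
  }
  invisible(x)
}

#' Error-function curve over candidate class counts
#'
#' Runs [fisher_partition()] for `k = 2 .. k_max` and reports the
#' (non-increasing) minimal error at each `k`, with a suggested class
#' count at the largest relative drop of the curve (including the drop
#' from the unsegmented total sum of squares at k = 1).
#'
#' @inheritParams fisher_partition
#' @param k_max largest class count to scan, `< length(x)`.
#' @return data.frame with columns `k`, `error_function`, `relative_drop`,
#'   plus attribute `suggested_k`.
#' @export
segmentation_scan <- function(x, k_max, standardize = TRUE) {
  n <- length(x)
  if (k_max >= n) stop("`k_max` must be < length(x)", call. = FALSE)
  fits <- lapply(2:k_max, function(k) {
    suppressWarnings(fisher_partition(x, k, standardize))
  })
  err <- vapply(fits, `[[`, numeric(1), "error_function")
  z <- as.numeric(x)
  if (standardize && !is.na(stats::sd(z)) && stats::sd(z) > 0) {
    z <- (z - mean(z)) / stats::sd(z)
  }
  e_prev <- c(sum((z - mean(z))^2), err[-length(err)])
  drop_rel <- ifelse(e_prev > 0, (e_prev - err) / e_prev, 0)
  out <- data.frame(k = 2:k_max, error_function = err,
                    relative_drop = drop_rel)
  attr(out, "suggested_k") <- out$k[which.max(drop_rel)]
  out
}

#' Ovarian development and mating summary per period
#'
#' Summarises dissection records within labelled periods: the mated rate
#' (fraction of females with at least one spermatophore), the matured rate
#' (fraction with ovarian development level above 2, i.e. egg maturation
#' onward), mean ovary level and mean mating count.
#'
#' @param series a [catch_series()] carrying dissection records.
#' @param period_fun function mapping a `Date` vector to period labels;
#'   defaults to [migration_season()].
#' @return data.frame with one row per period: `period`, `n_dissected`,
#'   `mated_rate`, `matured_rate`, `mean_ovary_level`,
#'   `mean_mating_count`. Periods with no records appear with `n_dissected
#'   = 0` and NA rates.
#' @export
ovary_summary <- function(series, period_fun = migration_season) {
  stopifnot(inherits(series, "catch_series"))
  d <- series$dissections
  if (is.null(d) || !nrow(d)) {
    stop("no dissection records in this series", call. = FALSE)
  }
  period <- period_fun(d$date)
  all_periods <- unique(period)
  rows <- lapply(all_periods, function(p) {
    sub <- d[period == p, ]
    data.frame(period = p, n_dissected = nrow(sub),
               mated_rate = mean(sub$mating_count >= 1),
               matured_rate = mean(sub$ovary_level > 2),
               mean_ovary_level = mean(sub$ovary_level),
               mean_mating_count = mean(sub$mating_count),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Monthly catch aggregates of a series
#'
#' Convenience for segmentation: the calendar-month aggregates (mean over
#' years of monthly totals, or pooled totals) as a named 12-vector in
#' month order.
#'
#' @param series a [catch_series()].
#' @param statistic `"mean"` (mean over years of the monthly total,
#'   default) or `"total"` (pooled).
#' @param what `"total"` (all moths) or `"females"`.
#' @return named numeric vector in calendar-month order (months present).
#' @export
monthly_aggregate <- function(series, statistic = c("mean", "total"),
                              what = c("total", "females")) {
  statistic <- match.arg(statistic)
  what <- match.arg(what)
  n <- series$nightly
  yr <- as.integer(format(n$date, "%Y"))
  mo <- as.integer(format(n$date, "%m"))
  v <- if (what == "total") n$total else n$females
  ym <- tapply(v, list(yr, mo), sum)
  agg <- apply(ym, 2, function(col) {
    col <- col[!is.na(col)]
    if (statistic == "mean") mean(col) else sum(col)
  })
  months <- as.integer(names(agg))
  out <- as.numeric(agg)
  names(out) <- month.abb[months]
  out[order(months)]
}
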