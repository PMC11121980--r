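# Region attribution: named polygon sets from GeoJSON, even-odd
# ray-casting point classification, and seasonal percentage tables of
# trajectory endpoints per region.

#' Build a region set from polygon coordinates
#'
#' @param polygons named list; each element is a list of rings, each ring a
#'   two-column matrix of (lon, lat) vertices. Multi-part regions and holes
#'   are handled by even-odd membership over all rings.
#' @param priority_order optional character vector fixing the order in
#'   which regions are tested; a point on a shared boundary belongs to the
#'   first region in this order that contains it. Defaults to the list
#'   order.
#' @return an object of class `"region_set"`.
#' @seealso [load_regions()], [classify_points()]
#' @export
region_set <- function(polygons, priority_order = names(polygons)) {
  nms <- names(polygons)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every region must be named", call. = FALSE)
  }
  if (anyDuplicated(nms)) {
    stop("duplicate region names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  if (!setequal(priority_order, nms)) {
    stop("priority_order must be a permutation of the region names",
         call. = FALSE)
  }
  polys <- lapply(polygons, function(rings) {
    lapply(rings, function(r) {
      r <- as.matrix(r)
      if (ncol(r) != 2L || nrow(r) < 3L || anyNA(r)) {
        stop("each ring must be a (lon, lat) matrix with >= 3 vertices",
             call. = FALSE)
      }
      # drop an explicit closing vertex; rings are treated as closed
      if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
      if (nrow(r) < 3L) stop("degenerate ring", call. = FALSE)
      unname(r)
    })
  })
  structure(list(polygons = polys[priority_order],
                 names = priority_order), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set with", length(x$names), "regions (priority order):\n")
  for (nm in x$names) {
    cat(sprintf("  %s (%d ring%s)\n", nm, length(x$polygons[[nm]]),
                if (length(x$polygons[[nm]]) > 1) "s" else ""))
  }
  invisible(x)
}

#' Load a region set from a GeoJSON FeatureCollection
#'
#' Features must be `Polygon` or `MultiPolygon` geometries with a `name`
#' property (property key configurable).
#'
#' @param path GeoJSON file path.
#' @param priority_order optional explicit ordering (see [region_set()]).
#' @param name_property property key holding the region name.
#' @return a [region_set()].
#' @export
load_regions <- function(path, priority_order = NULL,
                         name_property = "name") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("GeoJSON must be a FeatureCollection", call. = FALSE)
  }
  polys <- list()
  for (ft in gj$features) {
    nm <- ft$properties[[name_property]]
    if (is.null(nm) || !nzchar(nm)) {
      stop(sprintf("feature missing a `%s` property", name_property),
           call. = FALSE)
    }
    geom <- ft$geometry
    ring_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(xy) c(xy[[1]], xy[[2]])))
    }
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates, function(part) {
        lapply(part, ring_mat)
      }), recursive = FALSE),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    if (nm %in% names(polys)) {
      stop("duplicate region names: ", nm, call. = FALSE)
    }
    polys[[nm]] <- rings
  }
  region_set(polys, priority_order %||% names(polys))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Even-odd ray casting with a fixed east-pointing ray. Vertices lying
# exactly at the query latitude are nudged by 1e-12 degrees so the ray
# never passes through a vertex; a point exactly on an edge is contained.
point_in_rings <- function(lon, lat, rings) {
  inside <- FALSE
  for (r in rings) {
    n <- nrow(r)
    xs <- r[, 1]; ys <- r[, 2]
    ys[ys == lat] <- lat + 1e-12
    j <- n
    for (i in seq_len(n)) {
      # exact on-edge check (closed polygons contain their boundary)
      x1 <- xs[j]; y1 <- r[j, 2]; x2 <- xs[i]; y2 <- r[i, 2]
      if (on_segment(lon, lat, x1, y1, x2, y2)) return(TRUE)
      yi <- ys[i]; yj <- ys[j]
      if ((yi > lat) != (yj > lat)) {
        x_cross <- xs[i] + (lat - yi) / (yj - yi) * (xs[j] - xs[i])
        if (x_cross > lon) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

on_segment <- function(px, py, x1, y1, x2, y2) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > 1e-12 * max(1, abs(x2 - x1), abs(y2 - y1))) return(FALSE)
  px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
    py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12
}

#' Classify points into regions
#'
#' Each point is assigned to the first region in priority order whose
#' polygon (closed, boundary included) contains it, or `"other"` when no
#' region does.
#'
#' @param lat,lon numeric vectors of coordinates (degrees).
#' @param regions a [region_set()].
#' @return character vector of region names.
#' @export
classify_points <- function(lat, lon, regions) {
  stopifnot(inherits(regions, "region_set"), length(lat) == length(lon))
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  vapply(seq_along(lat), function(i) {
    for (nm in regions$names) {
      if (point_in_rings(lon[i], lat[i], regions$polygons[[nm]])) return(nm)
    }
    "other"
  }, character(1))
}

#' Attribute endpoints to regions by group
#'
#' Counts and percentages of points per region within each group (by
#' default the direction x season cells), shaped like a seasonal
#' source/landing attribution table. Percentages are
#' `100 * count / group total`, rounded half-up to one decimal.
#'
#' @param endpoints data.frame with `lat`, `lon` and the grouping columns
#'   (from [trajectory_endpoints()], [trajectory_points()] or
#'   [generate_endpoint_cloud()]).
#' @param regions a [region_set()].
#' @param group_keys character vector of grouping column names.
#' @param points_mode metadata string recording whether endpoints only or
#'   all trajectory points were supplied.
#' @return an object of class `"attribution_table"`: list with matrices
#'   `counts` and `percentages` (rows = regions + `"other"`, columns =
#'   groups), column totals `n`, and metadata.
#' @export
attribute_endpoints <- function(endpoints, regions,
                                group_keys = c("direction", "season"),
                                points_mode = "endpoints") {
  stopifnot(is.data.frame(endpoints), inherits(regions, "region_set"))
  missing_keys <- setdiff(c("lat", "lon", group_keys), names(endpoints))
  if (length(missing_keys)) {
    stop("endpoints lack columns: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(endpoints)) stop("no endpoints to attribute", call. = FALSE)
  labels <- classify_points(endpoints$lat, endpoints$lon, regions)
  grp <- if (length(group_keys)) {
    interaction(endpoints[group_keys], sep = "/", drop = TRUE,
                lex.order = TRUE)
  } else {
    factor(rep("all", nrow(endpoints)))
  }
  row_names <- c(regions$names, "other")
  counts <- table(factor(labels, levels = row_names), grp)
  counts <- matrix(as.integer(counts), nrow = length(row_names),
                   dimnames = list(region = row_names,
                                   group = colnames(counts)))
  n <- colSums(counts)
  empty <- n == 0
  if (any(empty)) {
    warning("empty group(s) omitted: ",
            paste(colnames(counts)[empty], collapse = ", "), call. = FALSE)
    counts <- counts[, !empty, drop = FALSE]
    n <- n[!empty]
  }
  pct <- sweep(counts, 2, n, "/") * 100
  pct <- round_half_up(pct, 1)
  structure(list(counts = counts, percentages = pct, n = n,
                 points_mode = points_mode, group_keys = group_keys),
            class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
  cat(sprintf("attribution_table (%s; groups: %s)\n", x$points_mode,
              paste(x$group_keys, collapse = " x ")))
  cat("\npercentages (%):\n")
  print(x$percentages)
  cat("\npoints per group:\n")
  print(x$n)
  invisible(x)
}

#' @export
as.data.frame.attribution_table <- function(x, ...) {
  df <- as.data.frame.table(as.table(x$percentages),
                            responseName = "percentage")
  cnt <- as.data.frame.table(as.table(x$counts), responseName = "count")
  df$count <- cnt$count
  df
}

#' Aggregate regions within an attribution table
#'
#' Sums the (rounded) percentages of member regions within each column;
#' used for derived shares such as a combined "South Asia" share.
#'
#' @param table an [attribute_endpoints()] result.
#' @param region_groups named list of character vectors; each vector a set
#'   of region names present in the table.
#' @return matrix: rows = groups, columns = the table's columns, values =
#'   summed percentages.
#' @examples
#' # a combined South Asia share from an India + Bangladesh split
#' @export
aggregate_regions <- function(table, region_groups) {
  stopifnot(inherits(table, "attribution_table"))
  rn <- rownames(table$percentages)
  rows <- lapply(region_groups, function(members) {
    unknown <- setdiff(members, rn)
    if (length(unknown)) {
      stop("unknown region(s) in group: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    colSums(table$percentages[members, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(names(region_groups),
                        colnames(table$percentages))
  out
}

#' Write an attribution table as CSV or Markdown
#'
#' @param table an [attribute_endpoints()] result.
#' @param path output path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_attribution <- function(table, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  pct <- table$percentages
  if (format == "csv") {
    df <- data.frame(region = rownames(pct), pct, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    hdr <- paste0("| Region | ", paste(colnames(pct), collapse = " | "),
                  " |")
    sep <- paste0("|", paste(rep("---", ncol(pct) + 1), collapse = "|"),
                  "|")
    rows <- vapply(rownames(pct), function(r) {
      paste0("| ", r, " | ",
             paste(sprintf("%.1f", pct[r, ]), collapse = " | "), " |")
    }, character(1))
    writeLines(c(hdr, sep, rows), path)
  }
  invisible(path)
}

#' Simplified four-country fixture regions
#'
#' Four disjoint rectangles labelled China, Myanmar, India and Bangladesh,
#' positioned in roughly their true relative geometry around the
#' China--Myanmar border monitoring area. These are synthetic test
#' geometries, NOT real national borders; analyses of real data must
#' supply their own boundary GeoJSON.
#'
#' @return a [region_set()].
#' @export
fixture_regions <- function() {
  load_regions(system.file("extdata", "regions_synthetic.geojson",
                           package = "mothtrack", mustWork = TRUE))
}
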