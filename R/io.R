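#' Read a cell coordinate table
#'
#' Reads a CSV with at least columns \code{x} and \code{y} and returns a
#' point pattern in micrometers. Coordinates recorded in pixels are converted
#' using the scanner pixel size (0.49 micrometers per pixel for 20x Aperio
#' scans is the typical value).
#'
#' @param path path to a CSV file (comma-separated, header required).
#' @param units \code{"micron"} (default) or \code{"pixel"}.
#' @param pixel_size micrometers per pixel; required when \code{units = "pixel"}.
#' @param window optional observation window passed to [point_pattern()];
#'   defaults to the bounding box of the points.
#' @return a \code{ppp}. An empty CSV (header only) yields an empty pattern.
#' @export
read_cells <- function(path, units = c("micron", "pixel"), pixel_size = NULL,
                       window = NULL) {
  units <- match.arg(units)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df))) {
    stop("cells CSV must contain columns 'x' and 'y': ", path)
  }
  x <- as.numeric(df$x); y <- as.numeric(df$y)
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) {
    stop("non-finite coordinate(s) in ", path, " at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  }
  if (units == "pixel") {
    if (is.null(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0) {
      stop("pixel_size (micrometers per pixel) is required when units = 'pixel'")
    }
    x <- x * pixel_size
    y <- y * pixel_size
  }
  point_pattern(x, y, window = window)
}

#' Write a cell coordinate table
#'
#' @param pp a point pattern.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cells <- function(pp, path) {
  write.csv(pattern_coords(pp), path, row.names = FALSE)
  invisible(path)
}

# ---- tissue region annotations -------------------------------------------

#' Construct a tissue region map
#'
#' A region map holds labeled tissue polygons (tumor / normal), an optional
#' derived invasive-front band, and the region-of-interest label. Polygon
#' coordinates are in micrometers. A polygon is a list with components
#' \code{x} and \code{y} (closed implicitly); holes are additional paths
#' associated with the same feature.
#'
#' @param polygons a list of elements \code{list(label =, paths = list(list(x=, y=), ...))},
#'   where the first path is the outer ring and any further paths are holes.
#' @return an object of class \code{region_map}.
#' @export
region_map <- function(polygons) {
  lab_ok <- c("tumor", "normal")
  for (i in seq_along(polygons)) {
    pg <- polygons[[i]]
    if (!is.list(pg) || is.null(pg$label) || is.null(pg$paths)) {
      stop("each region must be list(label=, paths=)")
    }
    if (!pg$label %in% lab_ok) {
      stop("region ", i, " has unknown label '", pg$label,
           "' (allowed: tumor, normal)")
    }
    for (p in pg$paths) {
      check_simple_polygon(p$x, p$y, where = paste0("region ", i))
    }
  }
  structure(list(polygons = polygons, invasive_front = NULL,
                 band_halfwidth = NA_real_, roi_label = NULL),
            class = "region_map")
}

# Reject self-intersecting rings (O(m^2) segment test; annotation rings are
# small).
check_simple_polygon <- function(x, y, where = "polygon") {
  m <- length(x)
  if (m != length(y) || m < 3L) stop(where, ": a ring needs >= 3 vertices")
  if (any(!is.finite(x) | !is.finite(y))) stop(where, ": non-finite vertex")
  # drop explicit closure
  if (x[1] == x[m] && y[1] == y[m]) { x <- x[-m]; y <- y[-m]; m <- m - 1L }
  if (m < 3L) stop(where, ": a ring needs >= 3 distinct vertices")
  if (abs(ring_area(x, y)) <= 0) stop(where, ": zero-area ring")
  seg <- cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
  for (i in seq_len(m - 2L)) {
    jj <- (i + 2L):m
    jj <- jj[!(i == 1L & jj == m)]   # skip segments sharing a vertex
    for (j in jj) {
      if (segments_cross(seg[i, ], seg[j, ])) {
        stop(where, ": self-intersecting ring (segments ", i, " and ", j, ")")
      }
    }
  }
  invisible(TRUE)
}

segments_cross <- function(s1, s2) {
  d <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- d(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2])
  d2 <- d(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4])
  d3 <- d(s2[1], s2[2], s2[3], s2[4], s1[1], s1[2])
  d4 <- d(s2[1], s2[2], s2[3], s2[4], s1[3], s1[4])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

ring_area <- function(x, y) {
  m <- length(x)
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# signed area summed over a polyclip-style path list (holes carry opposite
# orientation, so the sum is the net enclosed area)
paths_area <- function(paths) {
  if (!length(paths)) return(0)
  abs(sum(vapply(paths, function(p) ring_area(p$x, p$y), numeric(1))))
}

#' Read tissue region annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features, each with a property
#' \code{label} equal to \code{"tumor"} or \code{"normal"}. Coordinates are
#' interpreted in micrometers. Additional polygon rings are treated as holes.
#'
#' @param path path to a GeoJSON file.
#' @return a [region_map()] (invasive front unset; compute it with
#'   [build_invasive_front()]).
#' @export
read_regions <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("regions file must be a GeoJSON FeatureCollection")
  }
  polys <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    lab <- f$properties$label
    if (is.null(lab) || !lab %in% c("tumor", "normal")) {
      stop("feature ", i, " has missing/unknown label '",
           if (is.null(lab)) "<none>" else lab, "' (allowed: tumor, normal)")
    }
    if (is.null(f$geometry) || f$geometry$type != "Polygon") {
      stop("feature ", i, ": only Polygon geometries are supported")
    }
    paths <- lapply(f$geometry$coordinates, function(ring) {
      xy <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      list(x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2]))
    })
    list(label = lab, paths = paths)
  })
  region_map(polys)
}

#' Write a region map (and optional invasive front) to GeoJSON
#'
#' @param regions a [region_map()].
#' @param path output path.
#' @param include_front also emit the invasive-front band (as features labeled
#'   \code{invasive_front}) when it has been computed.
#' @return \code{path}, invisibly.
#' @export
write_regions <- function(regions, path, include_front = FALSE) {
  feat <- lapply(regions$polygons, function(pg) {
    list(type = "Feature",
         properties = list(label = pg$label),
         geometry = list(type = "Polygon",
                         coordinates = lapply(pg$paths, path_to_ring)))
  })
  if (include_front && length(regions$invasive_front)) {
    feat <- c(feat, lapply(regions$invasive_front, function(p) {
      list(type = "Feature",
           properties = list(label = "invasive_front"),
           geometry = list(type = "Polygon",
                           coordinates = list(path_to_ring(p))))
    }))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

path_to_ring <- function(p) {
  n <- length(p$x)
  closed <- (p$x[1] == p$x[n] && p$y[1] == p$y[n])
  idx <- if (closed) seq_len(n) else c(seq_len(n), 1L)
  lapply(idx, function(i) c(p$x[i], p$y[i]))
}

# ---- patient outcomes -----------------------------------------------------

#' Read a patient outcome table
#'
#' CSV with columns \code{patient_id}, \code{cohort} (MSI or MSS) and
#' \code{recist} (CR, PR, SD, PD). The derived responder flag is added by
#' [group_responders()].
#'
#' @param path path to CSV.
#' @return data frame with validated columns.
#' @export
read_outcomes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "cohort", "recist")
  if (!all(need %in% names(df))) {
    stop("outcomes CSV must have columns: ", paste(need, collapse = ", "))
  }
  df$cohort <- toupper(trimws(df$cohort))
  df$recist <- toupper(trimws(df$recist))
  if (!all(df$cohort %in% c("MSI", "MSS"))) {
    stop("unknown cohort code(s): ",
         paste(unique(setdiff(df$cohort, c("MSI", "MSS"))), collapse = ", "))
  }
  if (!all(df$recist %in% c("CR", "PR", "SD", "PD"))) {
    stop("unknown RECIST code(s): ",
         paste(unique(setdiff(df$recist, c("CR", "PR", "SD", "PD"))), collapse = ", "))
  }
  df
}
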