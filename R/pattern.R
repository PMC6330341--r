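#' Construct a cell point pattern
#'
#' Builds a planar point pattern (a \code{spatstat.geom::ppp} object) from
#' cell coordinates in micrometers. The observation window is an axis-aligned
#' rectangle; if none is supplied, the bounding box of the points is used.
#'
#' @param x,y numeric vectors of cell coordinates in micrometers.
#' @param window either \code{NULL} (bounding box of the points), a numeric
#'   vector \code{c(xmin, xmax, ymin, ymax)}, or an \code{owin}.
#' @return a \code{ppp} object with unitname micrometers.
#' @export
point_pattern <- function(x, y, window = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) && any(!is.finite(x) | !is.finite(y))) {
    bad <- which(!is.finite(x) | !is.finite(y))
    stop("non-finite coordinates at rows: ", paste(head(bad, 5L), collapse = ", "))
  }
  win <- resolve_window(window, x, y)
  if (length(x)) {
    inside <- spatstat.geom::inside.owin(x, y, win)
    if (!all(inside)) {
      stop(sum(!inside), " point(s) lie outside the observation window")
    }
  }
  spatstat.geom::ppp(x, y, window = win, unitname = c("micron", "microns"),
                     check = FALSE)
}

resolve_window <- function(window, x, y) {
  if (is.null(window)) {
    if (!length(x)) {
      return(spatstat.geom::owin(c(0, 1), c(0, 1), unitname = c("micron", "microns")))
    }
    rx <- range(x); ry <- range(y)
    # degenerate (single point / collinear) boxes get a token 1 um extent
    if (diff(rx) <= 0) rx <- rx + c(-0.5, 0.5)
    if (diff(ry) <= 0) ry <- ry + c(-0.5, 0.5)
    return(spatstat.geom::owin(rx, ry, unitname = c("micron", "microns")))
  }
  if (spatstat.geom::is.owin(window)) return(window)
  if (is.numeric(window) && length(window) == 4L) {
    if (window[2] <= window[1] || window[4] <= window[3]) {
      stop("window must have positive area")
    }
    return(spatstat.geom::owin(window[1:2], window[3:4],
                               unitname = c("micron", "microns")))
  }
  stop("window must be NULL, c(xmin, xmax, ymin, ymax), or an owin")
}

#' @export
#' @rdname point_pattern
#' @param pp a point pattern.
#' @return \code{pattern_coords}: a data frame with columns \code{x}, \code{y}.
pattern_coords <- function(pp) {
  data.frame(x = pp$x, y = pp$y)
}

window_area <- function(pp) spatstat.geom::area.owin(pp$window)
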