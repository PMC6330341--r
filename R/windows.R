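#' Moving-window grid specification
#'
#' Defaults follow the study conditions: 0.5 mm square windows moved in
#' 0.25 mm steps (50% overlap in each direction).
#'
#' @param x_window,y_window window edge lengths in micrometers.
#' @param x_step,y_step step sizes in micrometers (must not exceed the
#'   corresponding window length; overlap is allowed).
#' @return an object of class \code{window_grid}.
#' @export
window_grid <- function(x_window = 500, y_window = 500,
                        x_step = 250, y_step = 250) {
  v <- c(x_window, y_window, x_step, y_step)
  if (any(!is.finite(v)) || any(v <= 0)) stop("grid values must be positive")
  if (x_step > x_window || y_step > y_window) {
    stop("step sizes must not exceed window lengths")
  }
  structure(list(x_window = x_window, y_window = y_window,
                 x_step = x_step, y_step = y_step),
            class = "window_grid")
}

#' Extract moving-window sub-patterns
#'
#' Tiles the pattern's bounding window with rectangles of the grid's window
#' size placed every step. Window membership uses half-open intervals
#' \code{[x0, x0 + w) x [y0, y0 + h)} so that, when step equals window size,
#' every point falls in exactly one window. Only fully interior windows are
#' generated (positions \code{x0 = xmin + i * step} with
#' \code{x0 + w <= xmax}), so all windows have equal area.
#'
#' @param pp a point pattern.
#' @param grid a [window_grid()].
#' @return list of entries \code{list(window_id, x0, y0, pp)} where \code{pp}
#'   is the sub-pattern with the window rectangle as its observation window.
#' @export
extract_windows <- function(pp, grid) {
  stopifnot(inherits(grid, "window_grid"))
  fr <- pp$window
  xmin <- fr$xrange[1]; xmax <- fr$xrange[2]
  ymin <- fr$yrange[1]; ymax <- fr$yrange[2]
  eps <- 1e-9
  nx <- floor((xmax - xmin - grid$x_window) / grid$x_step + eps) + 1L
  ny <- floor((ymax - ymin - grid$y_window) / grid$y_step + eps) + 1L
  if (nx < 1L || ny < 1L) return(list())
  out <- vector("list", nx * ny)
  k <- 0L
  for (iy in seq_len(ny)) {
    y0 <- ymin + (iy - 1L) * grid$y_step
    for (ix in seq_len(nx)) {
      x0 <- xmin + (ix - 1L) * grid$x_step
      sel <- pp$x >= x0 & pp$x < x0 + grid$x_window &
             pp$y >= y0 & pp$y < y0 + grid$y_window
      sub <- spatstat.geom::ppp(pp$x[sel], pp$y[sel],
                                window = spatstat.geom::owin(
                                  c(x0, x0 + grid$x_window),
                                  c(y0, y0 + grid$y_window),
                                  unitname = c("micron", "microns")),
                                check = FALSE)
      k <- k + 1L
      out[[k]] <- list(window_id = sprintf("w%03d_%03d", ix, iy),
                       x0 = x0, y0 = y0, pp = sub)
    }
  }
  out
}
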