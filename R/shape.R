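#' Fit a confidence ellipse to cluster points
#'
#' Treats the member coordinates as draws from a bivariate normal
#' distribution and constructs the contour at the given confidence level.
#' With \eqn{\lambda_1 \ge \lambda_2} the eigenvalues of the sample
#' covariance, the semi-axes are \eqn{a = \sqrt{\lambda_1 \chi^2_2(level)}}
#' and \eqn{b = \sqrt{\lambda_2 \chi^2_2(level)}}
#' (\eqn{\chi^2_2(0.95) = 2\ln 20 \approx 5.991}), and the eccentricity is
#' \eqn{e = \sqrt{1 - \lambda_2/\lambda_1}}.
#'
#' @param points coordinates (micrometers); n >= 3.
#' @param level confidence level (default 0.95).
#' @return list with \code{lambda1}, \code{lambda2} (um^2), \code{a},
#'   \code{b} (um), \code{e}, \code{A_ellipse} (um^2), \code{center},
#'   \code{orientation} (radians of the major axis), \code{degenerate}
#'   (TRUE for a singular covariance: e = 1, zero area).
#' @export
fit_ellipse <- function(points, level = 0.95) {
  xy <- as_xy(points)
  if (nrow(xy) < 3L) stop("degenerate geometry: fewer than 3 points")
  S <- stats::cov(cbind(xy$x, xy$y))
  ellipse_from_cov(S, level = level, center = c(mean(xy$x), mean(xy$y)))
}

#' @rdname fit_ellipse
#' @param Sigma a 2x2 covariance matrix.
#' @param center optional ellipse center.
#' @export
ellipse_from_cov <- function(Sigma, level = 0.95, center = c(0, 0)) {
  eg <- eigen(Sigma, symmetric = TRUE)
  l1 <- eg$values[1]; l2 <- eg$values[2]
  chi <- qchisq(level, df = 2)
  tol <- max(abs(l1), 1) * 1e-12
  if (l2 <= tol) {
    return(list(lambda1 = l1, lambda2 = max(l2, 0), a = sqrt(max(l1, 0) * chi),
                b = 0, e = 1, A_ellipse = 0, center = center,
                orientation = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
                degenerate = TRUE))
  }
  a <- sqrt(l1 * chi); b <- sqrt(l2 * chi)
  list(lambda1 = l1, lambda2 = l2, a = a, b = b,
       e = sqrt(1 - l2 / l1), A_ellipse = pi * a * b, center = center,
       orientation = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       degenerate = FALSE)
}

#' Full morphometric summary of one detected cluster
#'
#' Composes the alpha-shape escalation, convex hull, shape descriptors and
#' confidence ellipse for the member points of a cluster. Clusters whose
#' geometry is degenerate (collinear, duplicated points) are returned with
#' \code{excluded = TRUE} and a reason instead of an error, so slide-level
#' summaries can proceed.
#'
#' @param points member coordinates (micrometers).
#' @param alpha_start starting alpha radius (default 10 um).
#' @param level ellipse confidence level (default 0.95).
#' @return a one-row data frame with columns n, alpha, A_alpha, P_alpha,
#'   A_conv, f_conv, f_circ, lambda1, lambda2, a, b, e, A_ellipse,
#'   density_mm2 (n / A_alpha in cells per mm^2), excluded, reason.
#' @export
summarize_cluster <- function(points, alpha_start = 10, level = 0.95) {
  xy <- as_xy(points)
  n <- nrow(xy)
  empty <- data.frame(n = n, alpha = NA_real_, A_alpha = NA_real_,
                      P_alpha = NA_real_, A_conv = NA_real_,
                      f_conv = NA_real_, f_circ = NA_real_,
                      lambda1 = NA_real_, lambda2 = NA_real_,
                      a = NA_real_, b = NA_real_, e = NA_real_,
                      A_ellipse = NA_real_, density_mm2 = NA_real_,
                      excluded = TRUE, reason = "", stringsAsFactors = FALSE)
  res <- tryCatch({
    ash <- alpha_shape_escalate(xy, alpha_start = alpha_start)
    A_conv <- convex_hull_area(xy)
    el <- fit_ellipse(xy, level = level)
    data.frame(n = n, alpha = ash$alpha, A_alpha = ash$area,
               P_alpha = ash$perimeter, A_conv = A_conv,
               f_conv = convexity(ash$area, A_conv),
               f_circ = circularity(ash$area, ash$perimeter),
               lambda1 = el$lambda1, lambda2 = el$lambda2,
               a = el$a, b = el$b, e = el$e, A_ellipse = el$A_ellipse,
               density_mm2 = n / um2_to_mm2(ash$area),
               excluded = el$degenerate,
               reason = if (el$degenerate) "singular covariance" else "",
               stringsAsFactors = FALSE)
  }, error = function(err) {
    out <- empty
    out$reason <- conditionMessage(err)
    out
  })
  res
}
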