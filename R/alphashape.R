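#' Alpha-shape of a point set with escalating alpha
#'
#' Computes the Delaunay alpha-complex of the points: triangles whose
#' circumradius is at most \code{alpha} are kept; the shape is their union,
#' its boundary the edges belonging to exactly one kept triangle. Starting
#' from \code{alpha_start}, alpha is multiplied by \code{factor} until the
#' shape is one single connected region that contains every input point and
#' has no interior holes (Euler characteristic 1); a bisection pass then
#' refines alpha between the last failing and first passing value.
#' Escalation always terminates because at alpha = max circumradius the
#' complex is the full triangulation of the convex hull, which satisfies
#' all three conditions.
#'
#' @param points data frame / matrix of coordinates (micrometers), or a ppp.
#' @param alpha_start initial alpha radius, micrometers (default 10).
#' @param factor multiplicative escalation factor (default 1.2).
#' @param refine_tol relative tolerance of the bisection refinement.
#' @return list with \code{alpha}, \code{area} (um^2), \code{perimeter}
#'   (um), \code{boundary_edges} (matrix of point indices), \code{triangles}
#'   (kept triangle vertex indices), \code{boundary_paths} (list of x/y loops
#'   when the boundary is manifold, otherwise NULL).
#' @export
alpha_shape_escalate <- function(points, alpha_start = 10, factor = 1.2,
                                 refine_tol = 1e-3) {
  xy <- as_xy(points)
  n <- nrow(xy)
  if (n < 3L) stop("degenerate geometry: fewer than 3 points")
  tri <- delaunay_triangles(xy$x, xy$y)
  if (!nrow(tri$idx)) stop("degenerate geometry: collinear points")

  ok <- function(alpha) {
    keep <- tri$circumradius <= alpha
    if (!any(keep)) return(FALSE)
    idx <- tri$idx[keep, , drop = FALSE]
    if (!all(seq_len(n) %in% as.vector(idx))) return(FALSE)
    if (!triangles_connected(idx)) return(FALSE)
    # simply connected: Euler characteristic V - E + F = 1 (no interior
    # holes); guaranteed at alpha = max circumradius (full triangulation
    # of the convex hull)
    e <- rbind(idx[, c(1, 2)], idx[, c(2, 3)], idx[, c(1, 3)])
    ne <- nrow(unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
    (n - ne + nrow(idx)) == 1L
  }

  alpha_max <- max(tri$circumradius)
  alpha <- alpha_start
  lo <- NA_real_
  while (!ok(alpha)) {
    lo <- alpha
    alpha <- alpha * factor
    if (alpha > alpha_max) { alpha <- alpha_max; break }
  }
  if (!ok(alpha)) {
    # numerically possible only through circumradius ties; nudge upward
    alpha <- alpha_max * (1 + 1e-9)
    if (!ok(alpha)) stop("degenerate geometry: no connected alpha-complex")
  }
  if (is.finite(lo) && !is.na(lo)) {
    hi <- alpha
    while ((hi - lo) / hi > refine_tol) {
      mid <- (lo + hi) / 2
      if (ok(mid)) hi <- mid else lo <- mid
    }
    alpha <- hi
  }

  keep <- tri$circumradius <= alpha
  idx <- tri$idx[keep, , drop = FALSE]
  area <- sum(tri$area[keep])
  be <- boundary_edges(idx)
  per <- sum(sqrt((xy$x[be[, 1]] - xy$x[be[, 2]])^2 +
                  (xy$y[be[, 1]] - xy$y[be[, 2]])^2))
  paths <- trace_boundary_loops(be, xy)
  list(alpha = alpha, area = area, perimeter = per,
       boundary_edges = be, triangles = idx, boundary_paths = paths)
}

# Delaunay triangulation via deldir; returns vertex-index triples with
# circumradius and area per triangle.
delaunay_triangles <- function(x, y) {
  if (anyDuplicated(cbind(x, y))) {
    # deldir drops duplicates silently; containment checks need the originals
    stop("degenerate geometry: duplicated points")
  }
  # collinear input has no triangulation (also trips deldir's own checks)
  cross <- (x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1])
  scale <- max(abs(c(x - x[1], y - y[1])), 1)
  if (all(abs(cross) <= 1e-9 * scale^2)) {
    stop("degenerate geometry: collinear points")
  }
  dd <- suppressMessages(deldir::deldir(x, y))
  tl <- deldir::triang.list(dd)
  if (!length(tl)) {
    return(list(idx = matrix(integer(0), 0, 3),
                circumradius = numeric(0), area = numeric(0)))
  }
  idx <- t(vapply(tl, function(tt) as.integer(tt$ptNum), integer(3)))
  ax <- x[idx[, 1]]; ay <- y[idx[, 1]]
  bx <- x[idx[, 2]]; by <- y[idx[, 2]]
  cx <- x[idx[, 3]]; cy <- y[idx[, 3]]
  la <- sqrt((bx - cx)^2 + (by - cy)^2)
  lb <- sqrt((ax - cx)^2 + (ay - cy)^2)
  lc <- sqrt((ax - bx)^2 + (ay - by)^2)
  ar <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
  cr <- ifelse(ar > 0, la * lb * lc / (4 * ar), Inf)
  list(idx = idx, circumradius = cr, area = ar)
}

# connectivity of the kept-triangle adjacency graph (triangles sharing an
# edge are adjacent)
triangles_connected <- function(idx) {
  nt <- nrow(idx)
  if (nt <= 1L) return(TRUE)
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(ek(idx[, 1], idx[, 2]), ek(idx[, 2], idx[, 3]), ek(idx[, 1], idx[, 3]))
  tri_of <- rep(seq_len(nt), 3L)
  bykey <- split(tri_of, keys)
  uf <- seq_len(nt)
  find <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  for (g in bykey) {
    if (length(g) > 1L) {
      r1 <- find(g[1L])
      for (t in g[-1L]) uf[find(t)] <- r1
    }
  }
  length(unique(vapply(seq_len(nt), find, integer(1)))) == 1L
}

# edges used by exactly one kept triangle
boundary_edges <- function(idx) {
  e <- rbind(cbind(idx[, 1], idx[, 2]),
             cbind(idx[, 2], idx[, 3]),
             cbind(idx[, 1], idx[, 3]))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  single <- names(cnt)[cnt == 1L]
  e[key %in% single, , drop = FALSE]
}

# assemble boundary edges into closed loops; returns NULL when a vertex has
# degree > 2 (pinched/non-manifold boundary)
trace_boundary_loops <- function(be, xy) {
  if (!nrow(be)) return(NULL)
  verts <- sort(unique(as.vector(be)))
  deg <- table(factor(as.vector(be), levels = verts))
  if (any(deg != 2L)) return(NULL)
  adj <- lapply(setNames(verts, verts), function(v) {
    r <- which(be[, 1] == v | be[, 2] == v)
    unique(setdiff(as.vector(be[r, ]), v))
  })
  visited <- setNames(logical(length(verts)), verts)
  loops <- list()
  for (v0 in verts) {
    if (visited[as.character(v0)]) next
    loop <- v0
    prev <- NA_integer_
    cur <- v0
    repeat {
      visited[as.character(cur)] <- TRUE
      nbr <- adj[[as.character(cur)]]
      nxt <- if (is.na(prev)) nbr[1L] else setdiff(nbr, prev)[1L]
      if (is.na(nxt) || nxt == v0) break
      loop <- c(loop, nxt)
      prev <- cur
      cur <- nxt
    }
    loops[[length(loops) + 1L]] <- list(x = xy$x[loop], y = xy$y[loop])
  }
  loops
}

#' Convex hull area of a point set
#' @param points coordinates (micrometers).
#' @return hull area in square micrometers.
#' @export
convex_hull_area <- function(points) {
  xy <- as_xy(points)
  h <- grDevices::chull(xy$x, xy$y)
  if (length(h) < 3L) return(0)
  abs(ring_area(xy$x[h], xy$y[h]))
}

#' Convexity of a cluster shape
#'
#' Ratio of the alpha-shape area to the convex-hull area; 1 for a convex
#' cluster, smaller for concave or branched shapes.
#'
#' @param A_alpha alpha-shape area.
#' @param A_conv convex hull area (same units).
#' @return proportion in (0, 1\].
#' @export
convexity <- function(A_alpha, A_conv) {
  if (!is.finite(A_conv) || A_conv <= 0) stop("degenerate geometry: zero hull area")
  stopifnot(A_alpha > 0, A_alpha <= A_conv * (1 + 1e-9))
  min(A_alpha / A_conv, 1)
}

#' Circularity (isoperimetric quotient) of a cluster shape
#'
#' \code{4 pi A / P^2}: 1 for a disk, small for elongated or ragged shapes.
#' Values marginally above 1 (possible only through numerical error) are
#' clipped with a warning.
#'
#' @param A_alpha alpha-shape area.
#' @param P_alpha alpha-shape perimeter.
#' @return proportion in (0, 1\].
#' @export
circularity <- function(A_alpha, P_alpha) {
  if (!is.finite(P_alpha) || P_alpha <= 0) stop("degenerate geometry: zero perimeter")
  f <- 4 * pi * A_alpha / P_alpha^2
  if (f > 1) {
    if (f > 1 + 1e-6) warning("circularity ", format(f), " > 1; clipped")
    f <- 1
  }
  f
}
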