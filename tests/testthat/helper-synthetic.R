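# shared fixture builders (all coordinates in micrometers)

# uniform sample from a disk
disk_points <- function(n, radius = 150, cx = 0, cy = 0) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

# uniform sample from a rotated rectangle (length along the rotated x axis)
strip_points <- function(n, len = 800, wid = 100, cx = 0, cy = 0, theta = 0) {
  u <- runif(n, -len / 2, len / 2)
  v <- runif(n, -wid / 2, wid / 2)
  data.frame(x = cx + u * cos(theta) - v * sin(theta),
             y = cy + u * sin(theta) + v * cos(theta))
}

rigid_motion <- function(xy, theta = 0, dx = 0, dy = 0) {
  data.frame(x = xy$x * cos(theta) - xy$y * sin(theta) + dx,
             y = xy$x * sin(theta) + xy$y * cos(theta) + dy)
}

# square tumor centered in a larger normal slide, both annotated
square_tumor_regions <- function(slide = c(0, 6000, 0, 6000),
                                 tumor = c(2000, 4000, 2000, 4000)) {
  tum <- list(x = tumor[c(1, 2, 2, 1)], y = tumor[c(3, 3, 4, 4)])
  sld <- list(x = slide[c(1, 2, 2, 1)], y = slide[c(3, 3, 4, 4)])
  region_map(list(list(label = "tumor", paths = list(tum)),
                  list(label = "normal", paths = list(sld, tum))))
}

# brute-force maximum matching size between two small point sets under a
# distance cap (independent oracle for the greedy matcher)
optimal_match_count <- function(a, b, radius) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(0L)
  d <- as.matrix(dist(rbind(a, b)))[seq_len(na), na + seq_len(nb), drop = FALSE]
  ok <- d <= radius
  small <- if (na <= nb) seq_len(na) else seq_len(nb)
  best <- 0L
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  large_n <- max(na, nb)
  for (p in perms(seq_len(large_n))) {
    cnt <- 0L
    for (i in small) {
      j <- p[i]
      hit <- if (na <= nb) ok[i, j] else ok[j, i]
      if (hit) cnt <- cnt + 1L
    }
    best <- max(best, cnt)
  }
  best
}
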