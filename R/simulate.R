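#' Specify a synthetic virtual slide
#'
#' A scenario bundles the region geometry, the per-region point process, the
#' planted cluster archetypes and the detection-noise model that together
#' define a virtual slide. Defaults describe a 4 x 4 mm slide with a central
#' 2 x 2 mm tumor: CD8+ T cells follow a Thomas cluster process inside the
#' tumor (40 clusters per mm^2, 15 cells per cluster, 25 um dispersion) and
#' a sparse uniform Poisson background (50 cells per mm^2) in the
#' surrounding normal tissue. Intensities are given per square millimeter;
#' lengths in micrometers.
#'
#' @param slide slide extent \code{c(xmin, xmax, ymin, ymax)}, micrometers.
#' @param tumor list of tumor polygon paths (\code{list(x =, y =)}); the
#'   default is the centered square covering a quarter of the slide. Use
#'   \code{list()} for a slide without tumor.
#' @param tumor_process,normal_process lists: either
#'   \code{list(type = "thomas", kappa_mm2 =, mu =, sigma =)} or
#'   \code{list(type = "poisson", lambda_mm2 =)} or \code{list(type = "none")}.
#' @param follicles circular archetypes:
#'   \code{list(count =, radius =, n_cells =)} (uniform disks).
#' @param strips elongated archetypes:
#'   \code{list(count =, length =, width =, n_cells =)} (uniform rotated
#'   rectangles).
#' @param miss_rate probability that a true cell is missed by detection.
#' @param false_rate_mm2 intensity of spurious detections, per mm^2.
#' @return an object of class \code{slide_scenario}.
#' @export
slide_scenario <- function(slide = c(0, 4000, 0, 4000),
                           tumor = NULL,
                           tumor_process = list(type = "thomas",
                                                kappa_mm2 = 40, mu = 15,
                                                sigma = 25),
                           normal_process = list(type = "poisson",
                                                 lambda_mm2 = 50),
                           follicles = list(count = 0, radius = 150,
                                            n_cells = 400),
                           strips = list(count = 0, length = 800,
                                         width = 100, n_cells = 300),
                           miss_rate = 0, false_rate_mm2 = 0) {
  stopifnot(length(slide) == 4, slide[2] > slide[1], slide[4] > slide[3],
            miss_rate >= 0, miss_rate < 1, false_rate_mm2 >= 0)
  if (is.null(tumor)) {
    cx <- mean(slide[1:2]); cy <- mean(slide[3:4])
    hw <- (slide[2] - slide[1]) / 4; hh <- (slide[4] - slide[3]) / 4
    tumor <- list(list(x = c(cx - hw, cx + hw, cx + hw, cx - hw),
                       y = c(cy - hh, cy - hh, cy + hh, cy + hh)))
  }
  structure(list(slide = slide, tumor = tumor,
                 tumor_process = tumor_process,
                 normal_process = normal_process,
                 follicles = follicles, strips = strips,
                 miss_rate = miss_rate, false_rate_mm2 = false_rate_mm2),
            class = "slide_scenario")
}

#' Simulate a virtual slide with ground truth
#'
#' Draws the per-region point processes, plants the archetype clusters,
#' applies the detection-noise model (independent thinning with the miss
#' rate plus uniform false detections) and assembles the region annotations.
#' The same seed reproduces the slide exactly.
#'
#' @param scenario a [slide_scenario()].
#' @param seed RNG seed.
#' @return list with \code{true} (data frame x, y, origin), \code{observed}
#'   (data frame x, y, true_index with NA for false detections),
#'   \code{regions} (a [region_map()]: tumor polygons plus the normal
#'   complement of the slide), and \code{manifest} (all parameters, the
#'   seed, and the realized counts).
#' @export
simulate_slide <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "slide_scenario"))
  if (!is.null(seed)) set.seed(seed)
  sl <- scenario$slide
  tum <- scenario$tumor
  have_tumor <- length(tum) > 0
  slide_ring <- list(x = sl[c(1, 2, 2, 1)], y = sl[c(3, 3, 4, 4)])

  pts <- list()
  add <- function(x, y, origin) {
    if (length(x)) {
      pts[[length(pts) + 1L]] <<- data.frame(x = x, y = y, origin = origin,
                                             stringsAsFactors = FALSE)
    }
  }
  if (have_tumor) {
    p <- sample_process_in_region(scenario$tumor_process, tum, sl)
    add(p$x, p$y, "tumor_process")
  }
  normal_paths <- c(list(slide_ring), if (have_tumor) tum)
  p <- sample_process_in_region(scenario$normal_process, normal_paths, sl)
  add(p$x, p$y, "normal_process")

  arch <- place_archetypes(scenario, sl)
  for (i in seq_along(arch)) {
    a <- arch[[i]]
    if (a$kind == "follicle") {
      rr <- a$radius * sqrt(runif(a$n))
      th <- runif(a$n, 0, 2 * pi)
      add(a$cx + rr * cos(th), a$cy + rr * sin(th), paste0("follicle_", a$id))
    } else {
      u <- runif(a$n, -a$len / 2, a$len / 2)
      v <- runif(a$n, -a$wid / 2, a$wid / 2)
      add(a$cx + u * cos(a$theta) - v * sin(a$theta),
          a$cy + u * sin(a$theta) + v * cos(a$theta),
          paste0("strip_", a$id))
    }
  }
  true <- if (length(pts)) do.call(rbind, pts) else
    data.frame(x = numeric(0), y = numeric(0), origin = character(0))
  # archetype points may spill outside the slide; clip
  keep <- true$x >= sl[1] & true$x <= sl[2] & true$y >= sl[3] & true$y <= sl[4]
  true <- true[keep, , drop = FALSE]
  rownames(true) <- NULL

  detected <- runif(nrow(true)) >= scenario$miss_rate
  obs <- data.frame(x = true$x[detected], y = true$y[detected],
                    true_index = which(detected))
  area_mm2 <- um2_to_mm2((sl[2] - sl[1]) * (sl[4] - sl[3]))
  n_false <- rpois(1, scenario$false_rate_mm2 * area_mm2)
  if (n_false > 0) {
    obs <- rbind(obs, data.frame(x = runif(n_false, sl[1], sl[2]),
                                 y = runif(n_false, sl[3], sl[4]),
                                 true_index = NA_integer_))
  }
  rownames(obs) <- NULL

  polys <- list()
  if (have_tumor) {
    polys <- lapply(tum, function(p) list(label = "tumor", paths = list(p)))
  }
  polys <- c(polys, list(list(label = "normal", paths = normal_paths)))
  regions <- region_map(polys)

  manifest <- list(scenario = unclass(scenario), seed = seed,
                   archetypes = arch,
                   n_true = nrow(true), n_observed = nrow(obs),
                   n_missed = sum(!detected), n_false = n_false)
  list(true = true, observed = obs, regions = regions, manifest = manifest)
}

sample_process_in_region <- function(proc, paths, slide) {
  none <- list(x = numeric(0), y = numeric(0))
  if (is.null(proc) || proc$type == "none" || !length(paths)) return(none)
  bx <- range(unlist(lapply(paths, `[[`, "x")))
  by <- range(unlist(lapply(paths, `[[`, "y")))
  win <- c(bx, by)
  if (proc$type == "poisson") {
    lam <- intensity_to_um2(proc$lambda_mm2)
    n <- rpois(1, lam * diff(bx) * diff(by))
    x <- runif(n, bx[1], bx[2]); y <- runif(n, by[1], by[2])
  } else if (proc$type == "thomas") {
    pp <- simulate_thomas(win, kappa = intensity_to_um2(proc$kappa_mm2),
                          mu = proc$mu, sigma = proc$sigma)
    x <- pp$x; y <- pp$y
  } else {
    stop("unknown process type: ", proc$type)
  }
  keep <- point_in_paths(x, y, paths)
  list(x = x[keep], y = y[keep])
}

# rejection placement of archetype centers: inside the slide with a margin,
# pairwise separated so planted clusters stay distinct
place_archetypes <- function(scenario, sl) {
  specs <- list()
  fo <- scenario$follicles; st <- scenario$strips
  if (!is.null(fo) && fo$count > 0) {
    for (i in seq_len(fo$count)) {
      specs[[length(specs) + 1L]] <- list(kind = "follicle", id = i,
                                          n = fo$n_cells, radius = fo$radius,
                                          extent = fo$radius)
    }
  }
  if (!is.null(st) && st$count > 0) {
    for (i in seq_len(st$count)) {
      specs[[length(specs) + 1L]] <- list(kind = "strip", id = i,
                                          n = st$n_cells, len = st$length,
                                          wid = st$width,
                                          extent = st$length / 2)
    }
  }
  if (!length(specs)) return(list())
  placed <- list()
  for (s in specs) {
    margin <- s$extent * 1.1
    lox <- sl[1] + margin; hix <- sl[2] - margin
    loy <- sl[3] + margin; hiy <- sl[4] - margin
    if (lox >= hix || loy >= hiy) {
      stop("archetype of extent ", s$extent, " um does not fit the slide")
    }
    ok <- FALSE
    for (try in 1:1000) {
      cx <- runif(1, lox, hix); cy <- runif(1, loy, hiy)
      sep_ok <- all(vapply(placed, function(p) {
        sqrt((p$cx - cx)^2 + (p$cy - cy)^2) >= 1.2 * (p$extent + s$extent)
      }, logical(1)))
      if (sep_ok) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place archetypes without overlap; reduce count or size")
    s$cx <- cx; s$cy <- cy
    if (s$kind == "strip") s$theta <- runif(1, 0, pi)
    placed[[length(placed) + 1L]] <- s
  }
  placed
}

#' Write a simulated slide to disk
#'
#' Emits \code{cells_true.csv}, \code{cells_observed.csv},
#' \code{regions.geojson} and \code{manifest.json} into a directory.
#'
#' @param sim result of [simulate_slide()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_slide <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sim$true, file.path(dir, "cells_true.csv"), row.names = FALSE)
  write.csv(sim$observed, file.path(dir, "cells_observed.csv"),
            row.names = FALSE)
  write_regions(sim$regions, file.path(dir, "regions.geojson"))
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
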