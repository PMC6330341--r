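#' Analysis configuration
#'
#' Collects every tunable of the per-slide workflow with its default:
#' 0.5 mm windows moved in 0.25 mm steps; at least 10 points per window for
#' CSR testing and model fitting; HDBSCAN with minPts 30 and K 4; alpha
#' escalation from 10 um; invasive-front half-width 250 um; minimum 50 cells
#' for the maximum-density metric; the circular/elongated threshold rules;
#' type-7 quartiles; significance level 0.05.
#'
#' @param x_window,y_window,x_step,y_step moving-window geometry (um).
#' @param n_min minimum points per window for testing/fitting.
#' @param minPts,K HDBSCAN parameters.
#' @param alpha_start alpha-shape starting radius (um).
#' @param band_halfwidth invasive-front half-width (um).
#' @param min_cells cluster-size floor for [max_cluster_density()].
#' @param prob_min minimum HDBSCAN membership strength for a point to enter
#'   a cluster's morphometrics (default 0.05); weakly attached stragglers
#'   otherwise distort the alpha-shape.
#' @param core_trim morphometrics also drop members whose core distance
#'   exceeds this multiple of the cluster's median core distance (default 3;
#'   \code{Inf} disables). Genuine boundary members sit within about twice
#'   the median while background stragglers are tens of times above it, so
#'   the rule is insensitive to the exact multiplier.
#' @param thresholds phenotype thresholds for [classify_cluster()].
#' @param quartile_type quartile convention for [qcod()].
#' @param alpha significance level of the CSR test.
#' @param ce_correction edge correction of [clark_evans_test()].
#' @return a named list of class \code{run_config}.
#' @export
run_config <- function(x_window = 500, y_window = 500,
                       x_step = 250, y_step = 250,
                       n_min = 10, minPts = 30, K = 4,
                       alpha_start = 10, band_halfwidth = 250,
                       min_cells = 50, prob_min = 0.05, core_trim = 3,
                       thresholds = list(),
                       quartile_type = 7, alpha = 0.05,
                       ce_correction = "donnelly") {
  structure(list(x_window = x_window, y_window = y_window,
                 x_step = x_step, y_step = y_step,
                 n_min = n_min, minPts = minPts, K = K,
                 alpha_start = alpha_start,
                 band_halfwidth = band_halfwidth,
                 min_cells = min_cells, prob_min = prob_min,
                 core_trim = core_trim, thresholds = thresholds,
                 quartile_type = quartile_type, alpha = alpha,
                 ce_correction = ce_correction),
            class = "run_config")
}

#' Run the full per-slide analysis
#'
#' Executes the two independent branches on the same coordinates — the
#' moving-window point-process branch (density, Clark-Evans CSR test, Thomas
#' fit with derived cluster statistics for aggregated windows) and the
#' morphometric branch (HDBSCAN clusters with alpha-shape / ellipse
#' descriptors and phenotype classification) — then, when annotations are
#' given, assigns tissue context to cells and clusters. Windows and clusters
#' skipped from fitting or morphometrics are retained in the tables with a
#' reason, so downstream summaries remain auditable.
#'
#' @param cells point pattern (or data frame) of cell coordinates.
#' @param regions optional [region_map()]; the invasive front is computed if
#'   missing.
#' @param config a [run_config()].
#' @param patient_id identifier carried into the summary.
#' @return list with \code{windows} (per-window table), \code{clusters}
#'   (per-cluster table), \code{summary} (from [intra_tumoral()]),
#'   \code{cell_labels}, \code{roi}, \code{regions}.
#' @export
run_slide <- function(cells, regions = NULL, config = run_config(),
                      patient_id = NA_character_) {
  pp <- if (spatstat.geom::is.ppp(cells)) cells else {
    xy <- as_xy(cells)
    point_pattern(xy$x, xy$y)
  }

  # ---- point-process branch ----
  grid <- window_grid(config$x_window, config$y_window,
                      config$x_step, config$y_step)
  wins <- extract_windows(pp, grid)
  wrows <- lapply(wins, function(w) {
    n <- w$pp$n
    dens <- n / um2_to_mm2(window_area(w$pp))
    row <- data.frame(window_id = w$window_id, x0 = w$x0, y0 = w$y0,
                      n = n, density_mm2 = dens,
                      ce_index = NA_real_, p_value = NA_real_,
                      verdict = "not_tested",
                      kappa = NA_real_, mu = NA_real_, sigma = NA_real_,
                      converged = NA,
                      mean_dist = NA_real_, r95 = NA_real_,
                      cluster_area = NA_real_,
                      skip_reason = "", stringsAsFactors = FALSE)
    if (n < config$n_min) {
      row$skip_reason <- "below n_min"
      return(row)
    }
    ce <- clark_evans_test(w$pp, alpha = config$alpha, n_min = config$n_min,
                           correction = config$ce_correction)
    row$ce_index <- ce$ce_index
    row$p_value <- ce$p_value
    row$verdict <- ce$verdict
    if (ce$verdict == "aggregated") {
      fit <- tryCatch(suppressWarnings(fit_thomas(w$pp, n_min = config$n_min)),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        row$kappa <- fit$kappa; row$mu <- fit$mu; row$sigma <- fit$sigma
        row$converged <- fit$converged
        ds <- derived_cluster_stats(fit)
        row$mean_dist <- ds$mean_dist
        row$r95 <- ds$r95
        row$cluster_area <- ds$cluster_area
        if (!fit$converged) row$skip_reason <- "fit not converged"
      } else {
        row$converged <- FALSE
        row$skip_reason <- "fit error"
      }
    } else {
      row$skip_reason <- "not aggregated"
    }
    row
  })
  windows <- if (length(wrows)) do.call(rbind, wrows) else
    data.frame(window_id = character(0))

  # ---- morphometric branch ----
  det <- detect_clusters(pp, minPts = config$minPts, K = config$K)
  core_members <- lapply(seq_along(det$members), function(i) {
    m <- det$members[[i]][det$member_prob[[i]] >= config$prob_min]
    cd <- det$core_dist[m]
    m[cd <= config$core_trim * median(cd)]
  })
  crows <- lapply(seq_along(core_members), function(i) {
    m <- summarize_cluster(pattern_coords(pp)[core_members[[i]], ],
                           alpha_start = config$alpha_start)
    cbind(data.frame(cluster_id = i), m)
  })
  clusters <- if (length(crows)) do.call(rbind, crows) else
    data.frame(cluster_id = integer(0), n = integer(0),
               density_mm2 = numeric(0), e = numeric(0),
               f_conv = numeric(0), f_circ = numeric(0),
               excluded = logical(0))
  if (nrow(clusters)) {
    ph <- classify_cluster(clusters$e, clusters$f_conv, clusters$f_circ,
                           thresholds = config$thresholds)
    clusters <- cbind(clusters, ph)
  }

  # ---- tissue context ----
  cell_labels <- NULL; roi <- NULL
  if (!is.null(regions)) {
    if (is.null(regions$invasive_front)) {
      regions <- build_invasive_front(regions, config$band_halfwidth)
    }
    roi <- select_roi(regions)
    cell_labels <- assign_cells(pp, regions)
    if (nrow(clusters)) {
      clusters$association <- associate_clusters(det$members,
                                                 cell_labels$label)
    }
  }

  summary <- tryCatch(
    intra_tumoral(windows, clusters, patient_id = patient_id,
                  type = config$quartile_type),
    error = function(e) NULL)

  list(windows = windows, clusters = clusters, summary = summary,
       cell_labels = cell_labels, roi = roi, regions = regions,
       patient_id = patient_id, members = det$members)
}

#' Cohort-level aggregation and outcome statistics
#'
#' Combines per-slide results into the inter-tumoral heterogeneity table
#' and, when outcomes are supplied, computes responder/non-responder
#' comparisons (Wilcoxon rank-sum) and the RECIST trend test for the
#' region-restricted cluster metrics: average cell density, maximum
#' within-cluster density, and counts of circular, elongated and all
#' clusters, each within the slide ROI (or the whole slide when
#' unannotated).
#'
#' @param slides named list of [run_slide()] results (names = patient ids).
#' @param outcomes optional outcome table (see [read_outcomes()]).
#' @param config a [run_config()].
#' @return list with \code{inter} (inter-tumoral QCoD table),
#'   \code{patient_metrics}, and \code{tests} (one row per metric).
#' @export
run_cohort <- function(slides, outcomes = NULL, config = run_config()) {
  stopifnot(length(slides) >= 2)
  ids <- names(slides)
  if (is.null(ids)) ids <- paste0("slide_", seq_along(slides))

  summaries <- Filter(Negate(is.null), lapply(slides, `[[`, "summary"))
  inter <- if (length(summaries) >= 2) inter_tumoral(summaries,
                                                     type = config$quartile_type)
           else NULL

  pm <- lapply(seq_along(slides), function(i) {
    s <- slides[[i]]
    cl <- s$clusters
    if (!is.null(s$roi) && nrow(cl) && "association" %in% names(cl)) {
      roi_assoc <- s$roi
      in_roi <- cl$association == roi_assoc
      areas <- region_areas(s$regions)
      roi_area <- unname(areas[roi_assoc])
      labs <- s$cell_labels$label
      roi_cells <- sum(labs == c(invasive_front = "peritumoral",
                                 tumor = "intratumoral",
                                 normal = "stromal")[roi_assoc])
      avg_density <- roi_cells / roi_area
      cl_roi <- cl[in_roi, , drop = FALSE]
    } else {
      cl_roi <- cl
      avg_density <- NA_real_
    }
    data.frame(patient_id = ids[i],
               avg_density = avg_density,
               max_cluster_density = max_cluster_density(cl_roi,
                                                         config$min_cells),
               n_circular = sum(cl_roi$is_circular, na.rm = TRUE),
               n_elongated = sum(cl_roi$is_elongated, na.rm = TRUE),
               n_clusters = nrow(cl_roi),
               stringsAsFactors = FALSE)
  })
  pm <- do.call(rbind, pm)

  tests <- NULL
  if (!is.null(outcomes)) {
    oc <- group_responders(outcomes)
    unmatched <- setdiff(pm$patient_id, oc$patient_id)
    if (length(unmatched)) {
      warning("no outcome for: ", paste(unmatched, collapse = ", "),
              "; skipped in tests")
    }
    mm <- merge(pm, oc, by = "patient_id")
    metric_cols <- c("avg_density", "max_cluster_density", "n_circular",
                     "n_elongated", "n_clusters")
    tests <- do.call(rbind, lapply(metric_cols, function(m) {
      w <- compare_groups(mm[[m]], mm$responder)
      tt <- tryCatch(
        trend_test(mm[[m]], factor(mm$recist,
                                   levels = c("PD", "SD", "PR", "CR"),
                                   ordered = TRUE)),
        error = function(e) list(J = NA_real_, p_value = NA_real_))
      data.frame(metric = m, W = w$W, p_wilcoxon = w$p_value,
                 J = tt$J, p_trend = tt$p_value, stringsAsFactors = FALSE)
    }))
  }
  list(inter = inter, patient_metrics = pm, tests = tests)
}
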