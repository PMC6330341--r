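#' Quartile coefficient of dispersion
#'
#' \code{QCoD = (Q3 - Q1) / (Q3 + Q1)}, a scale-free spread measure lying in
#' \[0, 1) for strictly positive inputs. Quartiles use linear interpolation
#' of order statistics (R's default, type 7); the convention is switchable
#' because the statistic is sensitive to it at small n.
#'
#' @param values numeric vector (at least 2 finite values).
#' @param type quantile algorithm type (default 7).
#' @return dispersion value.
#' @export
qcod <- function(values, type = 7) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) stop("QCoD undefined for fewer than 2 finite values")
  q <- quantile(v, probs = c(0.25, 0.75), type = type, names = FALSE)
  if (q[1] + q[2] == 0) stop("QCoD undefined: Q1 + Q3 = 0")
  (q[2] - q[1]) / (q[2] + q[1])
}

# window-branch metrics (converged fits only) and cluster-branch metrics
# (non-degenerate clusters only) entering the heterogeneity tables
window_metric_cols <- c("density_mm2", "mu", "mean_dist", "cluster_area")
cluster_metric_cols <- c("density_mm2", "n", "A_alpha", "A_ellipse",
                         "f_circ", "f_conv", "e")

#' Intra-tumoral heterogeneity of one slide
#'
#' Computes the QCoD of every point-process metric (over windows with a
#' converged Thomas fit) and every cluster metric (over non-degenerate
#' clusters), plus the per-metric median used as the patient's proxy value
#' for inter-tumoral comparison. Metrics with fewer than 2 values are
#' reported as missing.
#'
#' @param window_table per-window results (from [run_slide()]).
#' @param cluster_table per-cluster morphometrics (from [run_slide()]).
#' @param patient_id optional identifier carried through.
#' @param type quartile convention passed to [qcod()].
#' @return an object of class \code{slide_summary}: data frame with columns
#'   patient_id, branch, metric, n, median, qcod.
#' @export
intra_tumoral <- function(window_table = NULL, cluster_table = NULL,
                          patient_id = NA_character_, type = 7) {
  rows <- list()
  grab <- function(df, cols, branch, filter) {
    if (is.null(df) || !nrow(df)) return()
    df <- df[filter(df), , drop = FALSE]
    for (m in cols) {
      if (!m %in% names(df)) next
      v <- df[[m]][is.finite(df[[m]])]
      rows[[length(rows) + 1L]] <<- data.frame(
        patient_id = patient_id, branch = branch, metric = m,
        n = length(v),
        median = if (length(v)) median(v) else NA_real_,
        qcod = if (length(v) >= 2L) qcod(v, type = type) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  grab(window_table, window_metric_cols, "window",
       function(df) if ("converged" %in% names(df)) {
         !is.na(df$converged) & df$converged
       } else rep(TRUE, nrow(df)))
  # window density is meaningful for every window, fitted or not
  if (!is.null(window_table) && nrow(window_table)) {
    v <- window_table$density_mm2[is.finite(window_table$density_mm2)]
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = patient_id, branch = "window", metric = "density_all_mm2",
      n = length(v), median = if (length(v)) median(v) else NA_real_,
      qcod = if (length(v) >= 2L) qcod(v, type = type) else NA_real_,
      stringsAsFactors = FALSE)
  }
  grab(cluster_table, cluster_metric_cols, "cluster",
       function(df) if ("excluded" %in% names(df)) !df$excluded
                    else rep(TRUE, nrow(df)))
  if (!length(rows)) stop("no metrics available for this slide")
  out <- do.call(rbind, rows)
  class(out) <- c("slide_summary", class(out))
  out
}

#' Inter-tumoral heterogeneity across patients
#'
#' Applies [qcod()] to the vector of per-patient medians of each metric.
#'
#' @param summaries list of slide summaries from [intra_tumoral()].
#' @param type quartile convention.
#' @return data frame with branch, metric, n_patients, qcod.
#' @export
inter_tumoral <- function(summaries, type = 7) {
  stopifnot(length(summaries) >= 2L)
  all <- do.call(rbind, lapply(summaries, as.data.frame))
  keys <- unique(all[, c("branch", "metric")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- all$branch == keys$branch[i] & all$metric == keys$metric[i]
    med <- all$median[sel]
    med <- med[is.finite(med)]
    data.frame(branch = keys$branch[i], metric = keys$metric[i],
               n_patients = length(med),
               qcod = if (length(med) >= 2L) qcod(med, type = type) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
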