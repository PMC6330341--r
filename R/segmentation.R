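#' Match detected cells to a manually annotated reference set
#'
#' Mutually-greedy nearest-neighbor matching: pairs are formed in order of
#' increasing distance; a pair is accepted when both members are still
#' unmatched and the distance does not exceed \code{radius}. With inter-point
#' spacing above twice the radius this equals the optimal assignment.
#'
#' @param detected,reference point patterns (or data frames with x, y).
#' @param radius maximum pairing distance in micrometers (default 10, about
#'   one lymphocyte diameter).
#' @return list with counts \code{TP}, \code{FP}, \code{FN} and a data frame
#'   \code{pairs} (detected index, reference index, distance).
#' @export
match_points <- function(detected, reference, radius = 10) {
  stopifnot(radius > 0)
  d <- as_xy(detected); r <- as_xy(reference)
  nd <- nrow(d); nr <- nrow(r)
  pairs <- data.frame(detected = integer(0), reference = integer(0),
                      distance = numeric(0))
  if (nd && nr) {
    cand <- crosspairs_within(d, r, radius)
    if (nrow(cand)) {
      cand <- cand[order(cand$distance, cand$i, cand$j), , drop = FALSE]
      used_d <- logical(nd); used_r <- logical(nr)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (!used_d[i] && !used_r[j]) {
          used_d[i] <- TRUE; used_r[j] <- TRUE; keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- data.frame(detected = cand$i, reference = cand$j,
                          distance = cand$distance)
    }
  }
  TP <- nrow(pairs)
  list(TP = TP, FP = nd - TP, FN = nr - TP, pairs = pairs)
}

as_xy <- function(obj) {
  if (spatstat.geom::is.ppp(obj)) return(data.frame(x = obj$x, y = obj$y))
  if (is.data.frame(obj)) return(obj[, c("x", "y")])
  if (is.matrix(obj)) return(data.frame(x = obj[, 1], y = obj[, 2]))
  stop("expected a ppp, data frame or matrix of coordinates")
}

# all (i, j, distance) pairs with distance <= rmax, computed in blocks to
# bound memory
crosspairs_within <- function(d, r, rmax) {
  out <- list()
  block <- max(1L, floor(2e6 / max(1L, nrow(r))))
  for (s in seq(1L, nrow(d), by = block)) {
    e <- min(nrow(d), s + block - 1L)
    dx <- outer(d$x[s:e], r$x, "-")
    dy <- outer(d$y[s:e], r$y, "-")
    dist <- sqrt(dx * dx + dy * dy)
    hit <- which(dist <= rmax, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        i = hit[, 1] + s - 1L, j = hit[, 2],
        distance = dist[hit])
    }
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      distance = numeric(0)))
  do.call(rbind, out)
}

#' Recall (sensitivity) of cell detection
#'
#' \code{R = TP / (TP + FN)}: the fraction of manually identified cells that
#' the detector found.
#'
#' @param TP,FN true-positive and false-negative counts.
#' @return proportion in \[0, 1\].
#' @export
recall <- function(TP, FN) {
  if (TP + FN <= 0) stop("recall undefined: TP + FN = 0")
  TP / (TP + FN)
}

#' Precision (1 - false discovery rate) of cell detection
#'
#' \code{P = TP / (TP + FP)}.
#'
#' @param TP,FP true-positive and false-positive counts.
#' @return proportion in \[0, 1\].
#' @export
precision <- function(TP, FP) {
  if (TP + FP <= 0) stop("precision undefined: TP + FP = 0")
  TP / (TP + FP)
}

#' Binomial standard error of a proportion
#'
#' \code{sqrt(p (1 - p) / n)}; used for the standard errors of recall
#' (n = TP + FN) and precision (n = TP + FP).
#'
#' @param p proportion.
#' @param n denominator count.
#' @return standard error.
#' @export
se_proportion <- function(p, n) {
  if (n <= 0) stop("se undefined: n = 0")
  stopifnot(p >= 0, p <= 1)
  sqrt(p * (1 - p) / n)
}

#' Evaluate detection quality over many sampled regions
#'
#' Aggregates TP/FP/FN over sample regions, then computes pooled recall,
#' precision and their binomial standard errors, plus the Spearman rank
#' correlation between per-sample detected counts (TP + FP) and per-sample
#' reference counts (TP + FN). The correlation is reported as \code{NA} when
#' either count vector is constant.
#'
#' @param sample_pairs list of \code{list(detected =, reference =)} pairs of
#'   point patterns (one element per sampled region).
#' @param radius matching radius in micrometers.
#' @return list with \code{TP}, \code{FP}, \code{FN}, \code{R}, \code{P},
#'   \code{se_R}, \code{se_P}, \code{spearman_rho} and the per-sample count
#'   table \code{per_sample}.
#' @export
evaluate_samples <- function(sample_pairs, radius = 10) {
  stopifnot(length(sample_pairs) >= 1)
  per <- lapply(seq_along(sample_pairs), function(k) {
    sp <- sample_pairs[[k]]
    m <- match_points(sp$detected, sp$reference, radius = radius)
    data.frame(sample = k, TP = m$TP, FP = m$FP, FN = m$FN,
               n_detected = m$TP + m$FP, n_reference = m$TP + m$FN)
  })
  per <- do.call(rbind, per)
  TP <- sum(per$TP); FP <- sum(per$FP); FN <- sum(per$FN)
  if (TP + FN == 0 && TP + FP == 0) {
    stop("all samples empty: recall and precision undefined")
  }
  R <- recall(TP, FN)
  P <- precision(TP, FP)
  rho <- if (nrow(per) >= 2 && sd(per$n_detected) > 0 &&
             sd(per$n_reference) > 0) {
    cor(per$n_detected, per$n_reference, method = "spearman")
  } else NA_real_
  list(TP = TP, FP = FP, FN = FN,
       R = R, P = P,
       se_R = se_proportion(R, TP + FN),
       se_P = se_proportion(P, TP + FP),
       spearman_rho = rho,
       per_sample = per)
}

#' Place square evaluation regions over a slide
#'
#' Two sampling schemes for choosing square sub-regions used in manual-vs-
#' automatic detection comparisons: Latin hypercube sampling (default) and a
#' regular systematic grid.
#'
#' @param window numeric \code{c(xmin, xmax, ymin, ymax)} of the slide, in
#'   micrometers.
#' @param n number of regions.
#' @param size edge length of each square region (micrometers).
#' @param scheme \code{"lhs"} or \code{"systematic"}.
#' @param seed optional RNG seed (LHS only).
#' @return data frame of region origins \code{x0}, \code{y0} plus \code{size}.
#' @export
sample_eval_regions <- function(window, n, size,
                                scheme = c("lhs", "systematic"), seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(length(window) == 4, n >= 1, size > 0)
  W <- window[2] - window[1] - size
  H <- window[4] - window[3] - size
  if (W < 0 || H < 0) stop("region size exceeds the slide window")
  if (scheme == "lhs") {
    if (!is.null(seed)) set.seed(seed)
    u <- lhs::randomLHS(n, 2)
    out <- data.frame(x0 = window[1] + u[, 1] * W, y0 = window[3] + u[, 2] * H)
  } else {
    k <- ceiling(sqrt(n))
    gx <- window[1] + (seq_len(k) - 0.5) / k * W
    gy <- window[3] + (seq_len(k) - 0.5) / k * H
    g <- expand.grid(x0 = gx, y0 = gy)
    out <- g[seq_len(n), , drop = FALSE]
  }
  out$size <- size
  rownames(out) <- NULL
  out
}
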