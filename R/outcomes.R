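#' Classify a cluster phenotype from its shape descriptors
#'
#' Two archetypes motivated by tumor immuno-architecture: circular clusters
#' resembling lymphoid follicles (eccentricity < 0.8 AND convexity > 0.8 AND
#' circularity > 0.5) and elongated/irregular clusters resembling invasive-
#' front infiltrates (eccentricity > 0.9 OR convexity < 0.3 OR circularity
#' < 0.3). With the default thresholds the classes are disjoint and a
#' cluster may satisfy neither.
#'
#' @param e,f_conv,f_circ shape descriptors (vectors are accepted).
#' @param thresholds named list overriding any of \code{e_circ}
#'   (0.8), \code{conv_circ} (0.8), \code{circ_circ} (0.5), \code{e_elong}
#'   (0.9), \code{conv_elong} (0.3), \code{circ_elong} (0.3).
#' @return data frame with logical columns \code{is_circular} and
#'   \code{is_elongated}; degenerate descriptors (any NA) yield NA in both.
#' @export
classify_cluster <- function(e, f_conv, f_circ, thresholds = list()) {
  th <- utils::modifyList(list(e_circ = 0.8, conv_circ = 0.8, circ_circ = 0.5,
                               e_elong = 0.9, conv_elong = 0.3,
                               circ_elong = 0.3), thresholds)
  circ <- e < th$e_circ & f_conv > th$conv_circ & f_circ > th$circ_circ
  elong <- e > th$e_elong | f_conv < th$conv_elong | f_circ < th$circ_elong
  bad <- is.na(e) | is.na(f_conv) | is.na(f_circ)
  circ[bad] <- NA
  elong[bad] <- NA
  data.frame(is_circular = circ, is_elongated = elong)
}

#' Maximum within-cluster density in a region
#'
#' The highest cell density among clusters with at least \code{min_cells}
#' members (very small clusters are excluded); missing when no cluster
#' qualifies.
#'
#' @param cluster_table per-cluster table with columns \code{n} and
#'   \code{density_mm2}.
#' @param min_cells minimum member count to qualify (default 50).
#' @return density in cells per mm^2, or NA.
#' @export
max_cluster_density <- function(cluster_table, min_cells = 50) {
  if (is.null(cluster_table) || !nrow(cluster_table)) return(NA_real_)
  ok <- cluster_table$n >= min_cells & is.finite(cluster_table$density_mm2)
  if (!any(ok)) return(NA_real_)
  max(cluster_table$density_mm2[ok])
}

#' Derive responder flags from cohort and RECIST category
#'
#' MSI (mismatch-repair deficient) patients respond when the outcome is
#' complete or partial response; stable disease in an MSI patient is counted
#' as non-response because resistant clones are expected to progress. For
#' MSS patients stable disease counts as response.
#'
#' @param outcomes data frame with \code{cohort} and \code{recist} (see
#'   [read_outcomes()]).
#' @return the data frame with a logical \code{responder} column added.
#' @export
group_responders <- function(outcomes) {
  stopifnot(all(c("cohort", "recist") %in% names(outcomes)))
  if (!all(outcomes$cohort %in% c("MSI", "MSS"))) stop("unknown cohort code")
  if (!all(outcomes$recist %in% c("CR", "PR", "SD", "PD"))) stop("unknown RECIST code")
  outcomes$responder <- ifelse(
    outcomes$cohort == "MSI",
    outcomes$recist %in% c("CR", "PR"),
    outcomes$recist %in% c("CR", "PR", "SD"))
  outcomes
}

#' Compare a metric between responders and non-responders
#'
#' Two-sided Wilcoxon rank-sum test; exact when the combined sample size is
#' at most 20 and there are no ties, normal approximation with continuity
#' and tie correction otherwise. The reported statistic is the rank sum W of
#' the first (responder) group.
#'
#' @param values per-patient metric values.
#' @param responder logical flags, same length.
#' @param exact_max combined-n switch for the exact test (default 20).
#' @return list with \code{W} (rank sum of group 1), \code{p_value},
#'   \code{n1}, \code{n2}.
#' @export
compare_groups <- function(values, responder, exact_max = 20) {
  keep <- is.finite(values) & !is.na(responder)
  v <- values[keep]; g <- responder[keep]
  x <- v[g]; y <- v[!g]
  if (!length(x) || !length(y)) {
    return(list(W = NA_real_, p_value = NA_real_,
                n1 = length(x), n2 = length(y)))
  }
  ties <- anyDuplicated(v) > 0
  exact <- (length(v) <= exact_max) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  W <- unname(wt$statistic) + length(x) * (length(x) + 1) / 2
  list(W = W, p_value = wt$p.value, n1 = length(x), n2 = length(y))
}

#' Jonckheere-Terpstra trend test across ordered outcome groups
#'
#' Tests for an increasing trend of a metric across ordered groups (for
#' RECIST: PD < SD < PR < CR). The statistic is the sum over ordered group
#' pairs of Mann-Whitney counts (ties count 1/2). The p-value is one-sided
#' for an increasing trend, computed by complete enumeration of group-label
#' assignments when their number is small and by seeded random permutation
#' otherwise.
#'
#' @param values per-patient metric values.
#' @param groups ordered factor (or values coercible to one) of the same
#'   length; level order encodes the hypothesized trend.
#' @param n_perm number of random permutations (default 10000).
#' @param seed RNG seed for the permutation p-value (default 1).
#' @param enum_max exact enumeration is used when the number of distinct
#'   assignments is at most this (default 20000).
#' @return list with \code{J}, \code{p_value}, \code{n_groups},
#'   \code{method} ("exact" or "permutation").
#' @export
trend_test <- function(values, groups, n_perm = 10000, seed = 1,
                       enum_max = 20000) {
  keep <- is.finite(values) & !is.na(groups)
  v <- values[keep]
  g <- if (is.ordered(groups[keep])) droplevels(groups[keep]) else
    factor(groups[keep], levels = unique(groups[keep]), ordered = TRUE)
  ng <- nlevels(g)
  if (ng < 2L) stop("trend test needs at least 2 non-empty ordered groups")
  jstat <- function(vals, grp) {
    J <- 0
    for (i in seq_len(ng - 1L)) {
      for (j in (i + 1L):ng) {
        a <- vals[as.integer(grp) == i]
        b <- vals[as.integer(grp) == j]
        if (length(a) && length(b)) {
          cmp <- outer(a, b, "<")
          tie <- outer(a, b, "==")
          J <- J + sum(cmp) + sum(tie) / 2
        }
      }
    }
    J
  }
  J_obs <- jstat(v, g)
  sizes <- tabulate(as.integer(g), nbins = ng)
  n_assign <- round(exp(lgamma(length(v) + 1) - sum(lgamma(sizes + 1))))
  if (n_assign <= enum_max) {
    perms <- distinct_assignments(sizes)
    Js <- vapply(perms, function(lab) jstat(v, factor(levels(g)[lab],
                                                      levels = levels(g),
                                                      ordered = TRUE)),
                 numeric(1))
    p <- mean(Js >= J_obs - 1e-12)
    method <- "exact"
  } else {
    set.seed(seed)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      if (jstat(v, sample(g)) >= J_obs - 1e-12) cnt <- cnt + 1L
    }
    p <- (1 + cnt) / (1 + n_perm)
    method <- "permutation"
  }
  list(J = J_obs, p_value = p, n_groups = ng, method = method)
}

# all distinct assignments of group labels with the given sizes, as integer
# label vectors
distinct_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list(integer(n))
  avail <- list(seq_len(n))
  for (gi in seq_along(sizes)) {
    if (gi == length(sizes)) {
      for (k in seq_along(out)) out[[k]][avail[[k]]] <- gi
      break
    }
    new_out <- list(); new_avail <- list()
    for (k in seq_along(out)) {
      picks <- combn(avail[[k]], sizes[gi], simplify = FALSE)
      for (p in picks) {
        lab <- out[[k]]
        lab[p] <- gi
        new_out[[length(new_out) + 1L]] <- lab
        new_avail[[length(new_avail) + 1L]] <- setdiff(avail[[k]], p)
      }
    }
    out <- new_out; avail <- new_avail
  }
  out
}
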