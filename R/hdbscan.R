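#' Hierarchical density-based cluster detection (HDBSCAN)
#'
#' Detects cell clusters of variable density from slide coordinates.
#' The algorithm: (1) core distance of every point = distance to its K-th
#' nearest neighbor; (2) mutual reachability distance
#' \eqn{d_{mr}(a,b) = \max(core_a, core_b, d(a,b))}; (3) minimum spanning
#' tree of the complete mutual-reachability graph (Prim, O(n^2) time,
#' O(n) memory); (4) single-linkage hierarchy from the MST; (5) hierarchy
#' condensation with minimum cluster size \code{minPts}; (6) cluster
#' extraction by excess-of-mass stability. Points not in any stable cluster
#' are noise. The root (all-data) cluster is never selectable, so a slide
#' whose points form a single undifferentiated blob yields no clusters.
#'
#' When a branch smaller than \code{minPts} detaches, its points are recorded
#' as leaving the surviving cluster at the split level (a standard condensed-
#' tree simplification; per-point leave levels within a shed branch are not
#' tracked).
#'
#' Each member carries a membership strength in \[0, 1\]: the point's
#' density level at departure from the cluster, rescaled between the
#' cluster's birth and maximum level (as in common HDBSCAN
#' implementations). Core members score near 1; stray points that joined
#' the branch just above its birth level score near 0, which downstream
#' morphometrics use to trim them.
#'
#' @param pp point pattern, data frame, or two-column matrix of coordinates
#'   (micrometers).
#' @param minPts minimum points per cluster (default 30).
#' @param K core-distance neighborhood rank (default 4).
#' @return list with \code{labels} (integer vector, 0 = noise),
#'   \code{n_clusters}, \code{members} (list of index vectors, one per
#'   cluster, ordered by decreasing size), \code{member_prob} (parallel list
#'   of membership strengths), and \code{core_dist}.
#' @export
detect_clusters <- function(pp, minPts = 30, K = 4) {
  stopifnot(minPts >= 2, K >= 1)
  xy <- as_xy(pp)
  n <- nrow(xy)
  if (n < minPts) {
    return(list(labels = rep(0L, n), n_clusters = 0L,
                members = list(), member_prob = list(),
                core_dist = rep(NA_real_, n)))
  }
  x <- xy$x; y <- xy$y
  kk <- min(K, n - 1L)
  nnd <- spatstat.geom::nndist(x, y, k = kk)
  core <- if (is.matrix(nnd)) nnd[, kk] else nnd

  edges <- mst_mutual_reachability(x, y, core)
  hier <- single_linkage(edges, n)
  cond <- condense_tree(hier, n, minPts)
  sel <- extract_eom(cond)

  labels <- rep(0L, n)
  members <- list()
  member_prob <- list()
  for (s in sel) {
    mp <- cluster_member_points(cond, s)
    ord <- order(mp$points)
    pts <- mp$points[ord]
    lam <- mp$lambda[ord]
    birth <- cond$birth[s]
    lmax <- max(lam)
    prob <- if (lmax > birth) pmin(pmax((lam - birth) / (lmax - birth), 0), 1)
            else rep(1, length(lam))
    members[[length(members) + 1L]] <- pts
    member_prob[[length(member_prob) + 1L]] <- prob
  }
  if (length(members)) {
    ord <- order(vapply(members, length, integer(1)), decreasing = TRUE)
    members <- members[ord]
    member_prob <- member_prob[ord]
    for (i in seq_along(members)) labels[members[[i]]] <- i
  }
  list(labels = labels, n_clusters = length(members),
       members = members, member_prob = member_prob, core_dist = core)
}

# Prim's algorithm on the mutual-reachability graph; distances computed on
# the fly so memory stays O(n).
mst_mutual_reachability <- function(x, y, core) {
  n <- length(x)
  d_best <- rep(Inf, n)
  from <- integer(n)
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  cur <- 1L
  edges <- matrix(0, nrow = n - 1L, ncol = 3L)
  for (k in seq_len(n - 1L)) {
    dx <- x - x[cur]; dy <- y - y[cur]
    mr <- pmax(sqrt(dx * dx + dy * dy), core, core[cur])
    upd <- !in_tree & (mr < d_best)
    d_best[upd] <- mr[upd]
    from[upd] <- cur
    cand <- which(!in_tree)
    j <- cand[which.min(d_best[cand])]
    edges[k, ] <- c(from[j], j, d_best[j])
    in_tree[j] <- TRUE
    cur <- j
  }
  edges[order(edges[, 3]), , drop = FALSE]
}

# Single-linkage merge tree from sorted MST edges. Nodes 1..n are leaves;
# internal nodes n+1 .. 2n-1 are created in order of increasing merge height.
single_linkage <- function(edges, n) {
  m <- 2L * n - 1L
  L <- integer(m); R <- integer(m); H <- numeric(m)
  SZ <- c(rep(1L, n), integer(n - 1L))
  uf <- seq_len(n)              # union-find over points
  root_node <- seq_len(n)       # current tree node of each component root
  find <- function(i) {
    while (uf[i] != i) {
      uf[i] <<- uf[uf[i]]
      i <- uf[i]
    }
    i
  }
  nxt <- n
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1L]); rb <- find(edges[k, 2L])
    nxt <- nxt + 1L
    L[nxt] <- root_node[ra]; R[nxt] <- root_node[rb]
    H[nxt] <- edges[k, 3L]
    SZ[nxt] <- SZ[L[nxt]] + SZ[R[nxt]]
    uf[ra] <- rb
    root_node[rb] <- nxt
  }
  list(L = L, R = R, H = H, SZ = SZ, n = n, root = m)
}

subtree_leaves <- function(hier, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= hier$n) out <- c(out, v)
    else stack <- c(stack, hier$L[v], hier$R[v])
  }
  out
}

# Condensed tree: clusters appear at true splits (both children >= minPts);
# sub-minPts branches shed their points at the split level. Stability of a
# cluster is sum over its points of (lambda_leave - lambda_birth).
condense_tree <- function(hier, n, minPts) {
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_stab <- numeric(0)
  cl_children <- list(); cl_points <- list(); cl_plam <- list()
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_children[[length(cl_children) + 1L]] <<- integer(0)
    cl_points[[length(cl_points) + 1L]] <<- integer(0)
    cl_plam[[length(cl_plam) + 1L]] <<- numeric(0)
    id <- length(cl_parent)
    if (parent > 0L) cl_children[[parent]] <<- c(cl_children[[parent]], id)
    id
  }
  shed <- function(cid, node, lam) {
    pts <- subtree_leaves(hier, node)
    cl_points[[cid]] <<- c(cl_points[[cid]], pts)
    cl_plam[[cid]] <<- c(cl_plam[[cid]], rep(lam, length(pts)))
    cl_stab[cid] <<- cl_stab[cid] + length(pts) * (lam - cl_birth[cid])
  }
  root_cid <- new_cluster(0L, 0)
  stack_node <- hier$root
  stack_cid <- root_cid
  while (length(stack_node)) {
    node <- stack_node[length(stack_node)]; cid <- stack_cid[length(stack_cid)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cid <- stack_cid[-length(stack_cid)]
    repeat {
      if (node <= n) {  # lone point left in the cluster
        shed(cid, node, Inf_safe(hier$H, node))
        break
      }
      lam <- 1 / max(hier$H[node], .Machine$double.eps)
      l <- hier$L[node]; r <- hier$R[node]
      sl <- hier$SZ[l]; sr <- hier$SZ[r]
      if (sl >= minPts && sr >= minPts) {
        # true split: points present here survived to lam
        cl_stab[cid] <- cl_stab[cid] + hier$SZ[node] * (lam - cl_birth[cid])
        cid_l <- new_cluster(cid, lam)
        cid_r <- new_cluster(cid, lam)
        stack_node <- c(stack_node, r); stack_cid <- c(stack_cid, cid_r)
        node <- l; cid <- cid_l
      } else if (sl < minPts && sr < minPts) {
        shed(cid, l, lam); shed(cid, r, lam)
        break
      } else if (sl < minPts) {
        shed(cid, l, lam)
        node <- r
      } else {
        shed(cid, r, lam)
        node <- l
      }
    }
  }
  list(parent = cl_parent, birth = cl_birth, stability = cl_stab,
       children = cl_children, points = cl_points, plam = cl_plam)
}

# leave-level for a point that never merged below the current cluster: use
# the level at which it last connected (its own incident MST edge height is
# not tracked; the point persists to the end of the cluster)
Inf_safe <- function(H, node) {
  1 / .Machine$double.eps
}

# Excess-of-mass: bottom-up comparison of each cluster's stability with the
# summed stability of its selected descendants; the root is never selected.
extract_eom <- function(cond) {
  nc <- length(cond$parent)
  if (nc <= 1L) return(integer(0))
  sel_val <- numeric(nc)
  sel_set <- vector("list", nc)
  for (c in rev(seq_len(nc))) {
    kids <- cond$children[[c]]
    if (!length(kids)) {
      sel_val[c] <- cond$stability[c]
      sel_set[[c]] <- c
    } else {
      cv <- sum(sel_val[kids])
      if (c != 1L && cond$stability[c] >= cv) {
        sel_val[c] <- cond$stability[c]
        sel_set[[c]] <- c
      } else {
        sel_val[c] <- cv
        sel_set[[c]] <- unlist(sel_set[kids])
      }
    }
  }
  res <- sel_set[[1L]]
  res[res != 1L]   # a childless root means no stable cluster at all
}

# all points attached to cluster s or any condensed descendant, with the
# density level at which each departed
cluster_member_points <- function(cond, s) {
  pts <- integer(0)
  lam <- numeric(0)
  stack <- s
  while (length(stack)) {
    c <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pts <- c(pts, cond$points[[c]])
    lam <- c(lam, cond$plam[[c]])
    stack <- c(stack, cond$children[[c]])
  }
  list(points = pts, lambda = lam)
}
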