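# polygon boolean helpers (evenodd fill so ring orientation never matters;
# Clipper returns consistently oriented output)
paths_op <- function(A, B, op) {
  if (!length(A)) return(if (op == "union") normalize_paths(B) else list())
  if (!length(B)) return(if (op %in% c("union", "minus")) normalize_paths(A) else list())
  polyclip::polyclip(A, B, op = op, fillA = "evenodd", fillB = "evenodd")
}
normalize_paths <- function(A) {
  if (!length(A)) return(list())
  polyclip::polyclip(A, A, op = "union", fillA = "evenodd", fillB = "evenodd")
}
label_paths <- function(regions, label) {
  out <- list()
  for (pg in regions$polygons) {
    if (pg$label == label) out <- c(out, pg$paths)
  }
  normalize_paths(out)
}

#' Construct the invasive-front band of a region map
#'
#' The invasive front is the band extending \code{band_halfwidth}
#' micrometers on both sides of the tumor boundary where tumor meets
#' non-tumor tissue: the tumor outline is offset outward and inward by the
#' half-width, the ring between the two offsets is kept where it lies within
#' the half-width of annotated normal tissue, and the result is clipped to
#' the annotated tissue. A tumor edge that faces no normal tissue (e.g. the
#' slide margin) generates no band; a slide with no tumor gets an empty
#' front.
#'
#' @param regions a [region_map()].
#' @param band_halfwidth band half-width on each side of the boundary,
#'   micrometers (default 250).
#' @return the region map with \code{invasive_front} (a list of polygon
#'   paths, possibly empty) and \code{band_halfwidth} set.
#' @export
build_invasive_front <- function(regions, band_halfwidth = 250) {
  stopifnot(inherits(regions, "region_map"), band_halfwidth > 0)
  tum <- label_paths(regions, "tumor")
  nor <- label_paths(regions, "normal")
  front <- list()
  if (length(tum) && length(nor)) {
    h <- band_halfwidth
    outer <- polyclip::polyoffset(tum, h, jointype = "round")
    inner <- polyclip::polyoffset(tum, -h, jointype = "round")
    band <- paths_op(outer, inner, "minus")
    near_normal <- polyclip::polyoffset(nor, h, jointype = "round")
    front <- paths_op(band, near_normal, "intersection")
    tissue <- paths_op(tum, nor, "union")
    front <- paths_op(front, tissue, "intersection")
  }
  regions$invasive_front <- front
  regions$band_halfwidth <- band_halfwidth
  regions
}

#' Region-of-interest label for a slide
#'
#' Three-way fallback: all invasive fronts if any exist; otherwise all tumor
#' regions if any exist; otherwise all normal regions.
#'
#' @param regions a region map with the invasive front computed.
#' @return one of \code{"invasive_front"}, \code{"tumor"}, \code{"normal"}.
#' @export
select_roi <- function(regions) {
  stopifnot(inherits(regions, "region_map"))
  if (is.null(regions$invasive_front)) {
    stop("invasive front not computed; call build_invasive_front() first")
  }
  if (length(regions$invasive_front)) return("invasive_front")
  if (any(vapply(regions$polygons, function(p) p$label == "tumor", logical(1)))) {
    return("tumor")
  }
  if (any(vapply(regions$polygons, function(p) p$label == "normal", logical(1)))) {
    return("normal")
  }
  stop("region map contains no regions")
}

# even-odd containment over a list of paths
point_in_paths <- function(x, y, paths) {
  if (!length(paths)) return(rep(FALSE, length(x)))
  inside <- rep(0L, length(x))
  for (p in paths) {
    hit <- sp::point.in.polygon(x, y, p$x, p$y) > 0
    inside <- inside + as.integer(hit)
  }
  inside %% 2L == 1L
}

#' Assign a tissue context to every cell
#'
#' Cells inside the invasive-front band are peritumoral; remaining cells
#' inside a tumor region are intratumoral; everything else is stromal. The
#' three classes are mutually exclusive. Cells outside all annotated regions
#' are stromal with \code{out_of_annotation = TRUE}.
#'
#' @param pp point pattern of cells.
#' @param regions region map with the invasive front computed.
#' @return data frame with columns \code{label} (intratumoral / peritumoral
#'   / stromal) and \code{out_of_annotation}.
#' @export
assign_cells <- function(pp, regions) {
  stopifnot(inherits(regions, "region_map"))
  if (is.null(regions$invasive_front)) {
    stop("invasive front not computed; call build_invasive_front() first")
  }
  xy <- as_xy(pp)
  tum <- label_paths(regions, "tumor")
  nor <- label_paths(regions, "normal")
  in_front <- point_in_paths(xy$x, xy$y, regions$invasive_front)
  in_tum <- point_in_paths(xy$x, xy$y, tum)
  in_nor <- point_in_paths(xy$x, xy$y, nor)
  label <- ifelse(in_front, "peritumoral",
                  ifelse(in_tum, "intratumoral", "stromal"))
  data.frame(label = label,
             out_of_annotation = !(in_front | in_tum | in_nor),
             stringsAsFactors = FALSE)
}

#' Tissue association of detected clusters
#'
#' A cluster with any peritumoral member is invasive-front associated;
#' otherwise a cluster with any intratumoral member is tumor associated;
#' all remaining clusters are normal-tissue associated.
#'
#' @param members list of member-index vectors (from [detect_clusters()]).
#' @param cell_labels per-cell labels (from [assign_cells()]), either the
#'   data frame or its \code{label} column.
#' @return character vector, one association per cluster.
#' @export
associate_clusters <- function(members, cell_labels) {
  if (is.data.frame(cell_labels)) cell_labels <- cell_labels$label
  vapply(members, function(idx) {
    lab <- cell_labels[idx]
    if (any(lab == "peritumoral")) "invasive_front"
    else if (any(lab == "intratumoral")) "tumor"
    else "normal"
  }, character(1))
}

#' Mutually exclusive region areas of an annotated slide
#'
#' Areas (mm^2) of the invasive-front band, the tumor core (tumor minus
#' band) and distal normal tissue (normal minus band) — the denominators
#' matching the mutually exclusive cell classes of [assign_cells()].
#'
#' @param regions region map with the invasive front computed.
#' @return named numeric vector (mm^2): invasive_front, tumor, normal.
#' @export
region_areas <- function(regions) {
  stopifnot(inherits(regions, "region_map"))
  if (is.null(regions$invasive_front)) {
    stop("invasive front not computed; call build_invasive_front() first")
  }
  tum <- label_paths(regions, "tumor")
  nor <- label_paths(regions, "normal")
  front <- regions$invasive_front
  c(invasive_front = um2_to_mm2(paths_area(front)),
    tumor = um2_to_mm2(paths_area(paths_op(tum, front, "minus"))),
    normal = um2_to_mm2(paths_area(paths_op(nor, front, "minus"))))
}
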