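#' Surveyor's (shoelace) polygon area and centroid
#'
#' Closed-form area and centroid of a simple polygon from its ordered
#' vertices, the surveyor's area formula. Used on the convex hulls of
#' detected nano-clusters.
#'
#' @param vertices numeric matrix (k x 2) of polygon vertices in order
#'   (either orientation); the polygon is closed implicitly.
#' @return `shoelace_area()`: the (unsigned) area in the squared input
#'   unit. `shoelace_centroid()`: numeric length-2 centroid; for degenerate
#'   polygons (fewer than 3 vertices or zero area) the vertex mean, with
#'   attribute `degenerate = TRUE`.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' shoelace_area(sq)
#' shoelace_centroid(sq)
#' @export
shoelace_area <- function(vertices) {
  abs(shoelace_signed_area(vertices))
}

shoelace_signed_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @rdname shoelace_area
#' @export
shoelace_centroid <- function(vertices) {
  v <- as.matrix(vertices)
  a <- shoelace_signed_area(v)
  if (nrow(v) < 3 || abs(a) < 1e-12 * max(1, max(abs(v)))^2) {
    return(structure(colMeans(v), degenerate = TRUE))
  }
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# hull of a point set: ordered vertex matrix (may have < 3 rows when
# degenerate)
hull_vertices <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3) return(xy)
  xy[grDevices::chull(xy), , drop = FALSE]
}

#' Cluster geometry accessors
#'
#' Geometry of a detected nano-cluster: the polygon centroid of its convex
#' hull by the surveyor's (shoelace) formula, the hull area in um^2, and
#' the root-mean-square distance of the hull vertices to the centroid as a
#' size measure. Degenerate clusters (collinear points) fall back to the
#' member mean / zero area / RMS over all member points, and are flagged
#' via `cluster$degenerate`.
#'
#' @param cluster an `smlm_cluster`, as returned in the list from
#'   [detect_clusters()].
#' @return `cluster_centroid()`: numeric length-2 in nm. `cluster_area()`:
#'   area in um^2. `cluster_size_rms()`: size in nm.
#' @export
cluster_centroid <- function(cluster) cluster$centroid_nm

#' @rdname cluster_centroid
#' @export
cluster_area <- function(cluster) cluster$area_um2

#' @rdname cluster_centroid
#' @param method `"vertex_centroid"` (default): RMS of hull-vertex to
#'   centroid distances; `"pairwise"`: RMS over all pairwise hull-vertex
#'   distances.
#' @export
cluster_size_rms <- function(cluster,
                             method = c("vertex_centroid", "pairwise")) {
  method <- match.arg(method)
  if (method == "vertex_centroid") return(cluster$rms_nm)
  v <- cluster$hull_nm
  if (nrow(v) < 2) return(0)
  sqrt(mean(stats::dist(v)^2))
}

# build an smlm_cluster object from member coordinates
make_cluster <- function(id, members, xy) {
  pts <- xy[members, , drop = FALSE]
  hull <- hull_vertices(pts)
  centroid <- shoelace_centroid(hull)
  degenerate <- isTRUE(attr(centroid, "degenerate"))
  area_nm2 <- if (degenerate) 0 else shoelace_area(hull)
  rms <- if (degenerate) {
    ctr <- colMeans(pts)
    sqrt(mean((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2))
  } else {
    sqrt(mean((hull[, 1] - centroid[1])^2 + (hull[, 2] - centroid[2])^2))
  }
  structure(list(id = id, members = members, n_points = length(members),
                 hull_nm = hull, centroid_nm = as.numeric(centroid),
                 area_um2 = area_nm2 / 1e6, rms_nm = rms,
                 hc_label = NA_character_, degenerate = degenerate),
            class = "smlm_cluster")
}

#' @export
print.smlm_cluster <- function(x, ...) {
  cat(sprintf(
    "<smlm_cluster #%s> %d points, area %.4f um^2, rms %.1f nm%s%s\n",
    x$id, x$n_points, x$area_um2, x$rms_nm,
    if (!is.na(x$hc_label)) paste0(", ", x$hc_label) else "",
    if (x$degenerate) " (degenerate hull)" else ""))
  invisible(x)
}
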