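#' Nano-cluster detection criteria
#'
#' Parameters of the density-based cluster definition: a point belongs to a
#' cluster core when at least `min_points` events (itself included) lie
#' within `neighborhood_radius_nm`; cores within that radius of each other
#' are density-connected into one cluster and remaining events within the
#' radius of a core join it as border points. Clusters exceeding
#' `max_points` members or whose hull diameter exceeds `max_extent_nm` are
#' discarded post hoc.
#'
#' @param neighborhood_radius_nm neighbourhood radius (DBSCAN eps) in nm.
#' @param min_points minimum number of cluster points (also the core
#'   threshold and minimum reported cluster size).
#' @param max_points maximum cluster size (default unlimited).
#' @param max_extent_nm maximum distance between points within a cluster,
#'   enforced on the hull diameter (default unlimited).
#' @return An object of class `cluster_criteria`.
#' @seealso [cluster_preset()] for the published parameter sets.
#' @export
cluster_criteria <- function(neighborhood_radius_nm, min_points,
                             max_points = Inf, max_extent_nm = Inf) {
  if (!isTRUE(neighborhood_radius_nm > 0))
    stop("`neighborhood_radius_nm` must be > 0", call. = FALSE)
  if (min_points < 1) stop("`min_points` must be >= 1", call. = FALSE)
  if (max_points < min_points)
    stop("`max_points` must be >= `min_points`", call. = FALSE)
  structure(list(neighborhood_radius_nm = as.numeric(neighborhood_radius_nm),
                 min_points = as.integer(min_points),
                 max_points = max_points,
                 max_extent_nm = as.numeric(max_extent_nm)),
            class = "cluster_criteria")
}

#' Published cluster-criteria presets
#'
#' * `gammaH2AX_fig4`: radius 200 nm, minimum 46 points (gammaH2AX
#'   nano-cluster counting).
#' * `gammaH2AX_topology`: radius 200 nm, minimum 50 points (cluster
#'   definition used for the topological comparisons).
#' * `nucleosome`: more than three points within a 40-nm radius, at most
#'   100 points per cluster and at most 200 nm between cluster points.
#'
#' @param name preset name.
#' @return A [cluster_criteria()].
#' @export
cluster_preset <- function(name = c("gammaH2AX_fig4", "gammaH2AX_topology",
                                    "nucleosome")) {
  switch(match.arg(name),
         gammaH2AX_fig4 = cluster_criteria(200, 46),
         gammaH2AX_topology = cluster_criteria(200, 50),
         nucleosome = cluster_criteria(40, 4, max_points = 100,
                                       max_extent_nm = 200))
}

# eps-neighbourhood lists (self included) via a grid of eps-sized cells
eps_neighbors <- function(xy, eps) {
  n <- nrow(xy)
  if (n == 0) return(list())
  cx <- as.integer(floor((xy[, 1] - min(xy[, 1])) / eps))
  cy <- as.integer(floor((xy[, 2] - min(xy[, 2])) / eps))
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  lookup <- new.env(parent = emptyenv(), size = length(buckets))
  for (k in names(buckets)) assign(k, buckets[[k]], envir = lookup)
  eps2 <- eps^2
  lapply(seq_len(n), function(i) {
    cand <- integer()
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      b <- lookup[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
    sort(cand[d2 <= eps2])
  })
}

#' Detect nano-clusters by density connectivity
#'
#' DBSCAN-style detection: core points (at least `min_points` events within
#' the neighbourhood radius, self included) are density-connected into
#' clusters; non-core events within the radius of a core join the cluster
#' of their lowest-index core neighbour (a deterministic tie rule). Every
#' reported cluster satisfies all criteria: size within
#' `[min_points, max_points]` and hull diameter at most `max_extent_nm`.
#'
#' @param points a [localization_table()], data.frame or 2-column matrix.
#' @param criteria a [cluster_criteria()] or preset name (see
#'   [cluster_preset()]).
#' @return A list of class `smlm_clusters` of `smlm_cluster` objects, each
#'   with member indices, convex hull, shoelace centroid (nm), hull area
#'   (um^2) and RMS size (nm). Empty input gives an empty list.
#' @examples
#' sim <- simulate_clustered(cluster_pattern_spec(3, 60, 50,
#'                                                min_separation_nm = 2000),
#'                           field_spec(10000), seed = 1)
#' length(detect_clusters(sim$events, cluster_criteria(200, 46)))
#' @export
detect_clusters <- function(points, criteria) {
  if (is.character(criteria)) criteria <- cluster_preset(criteria)
  stopifnot(inherits(criteria, "cluster_criteria"))
  xy <- loc_xy(points)
  n <- nrow(xy)
  if (n == 0) return(structure(list(), class = "smlm_clusters"))
  eps <- criteria$neighborhood_radius_nm
  nb <- eps_neighbors(xy, eps)
  core <- lengths(nb) >= criteria$min_points
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      nbc <- nb[[j]]
      nbc <- nbc[core[nbc] & labels[nbc] == 0L]
      labels[nbc] <- cl
      queue <- c(queue, nbc)
    }
  }
  # border points: cluster of the lowest-index core neighbour
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    cores_near <- nb[[i]][core[nb[[i]]]]
    if (length(cores_near)) labels[i] <- labels[min(cores_near)]
  }
  clusters <- list()
  for (k in seq_len(cl)) {
    members <- which(labels == k)
    if (length(members) < criteria$min_points ||
        length(members) > criteria$max_points) next
    obj <- make_cluster(length(clusters) + 1L, members, xy)
    if (is.finite(criteria$max_extent_nm) && nrow(obj$hull_nm) >= 2 &&
        max(stats::dist(obj$hull_nm)) > criteria$max_extent_nm) next
    obj$id <- length(clusters) + 1L
    clusters[[length(clusters) + 1L]] <- obj
  }
  structure(clusters, criteria = criteria, class = "smlm_clusters")
}

#' @export
print.smlm_clusters <- function(x, ...) {
  cat(sprintf("<smlm_clusters> %d cluster(s)\n", length(x)))
  invisible(x)
}

#' Summarise detected clusters as a data frame
#'
#' One row per cluster with the export columns
#' `cluster_id,n_points,centroid_x_nm,centroid_y_nm,area_um2,rms_nm,hc_label`.
#'
#' @param x an `smlm_clusters` list.
#' @param ... unused.
#' @export
as.data.frame.smlm_clusters <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(cluster_id = integer(), n_points = integer(),
                      centroid_x_nm = numeric(), centroid_y_nm = numeric(),
                      area_um2 = numeric(), rms_nm = numeric(),
                      hc_label = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x, function(cl) {
    data.frame(cluster_id = cl$id, n_points = cl$n_points,
               centroid_x_nm = cl$centroid_nm[1],
               centroid_y_nm = cl$centroid_nm[2],
               area_um2 = cl$area_um2, rms_nm = cl$rms_nm,
               hc_label = cl$hc_label, stringsAsFactors = FALSE)
  }))
}

#' Quality-control filter on per-cell signal counts
#'
#' Keeps cells (localization tables) whose event count lies within the
#' selection window, by default 10,000 to 50,000 signals per cell.
#'
#' @param tables list of localization tables, one per cell.
#' @param min_signals,max_signals inclusive bounds.
#' @return The filtered list; the indices of the kept tables are in
#'   attribute `kept`.
#' @export
qc_filter_cells <- function(tables, min_signals = 10000,
                            max_signals = 50000) {
  stopifnot(min_signals > 0, min_signals <= max_signals)
  n <- vapply(tables, nrow, integer(1))
  keep <- n >= min_signals & n <= max_signals
  structure(tables[keep], kept = which(keep))
}

#' Fraction of events belonging to a cluster
#'
#' @param points the localization table the clusters were detected in.
#' @param clusters an `smlm_clusters` list from [detect_clusters()].
#' @return Percentage (0-100) of events that are members of any reported
#'   cluster. An empty table is an error (the fraction is undefined).
#' @export
fraction_clustered <- function(points, clusters) {
  n <- nrow(loc_xy(points))
  if (n == 0)
    stop("fraction_clustered is undefined for an empty table", call. = FALSE)
  members <- unique(unlist(lapply(clusters, `[[`, "members")))
  100 * length(members) / n
}

#' Cluster counts per cell with a boxplot-style summary
#'
#' Runs [detect_clusters()] on every cell and summarises the per-cell
#' counts (median, quartiles, mean +/- 2 SD).
#'
#' @param tables list of localization tables, one per cell.
#' @param criteria a [cluster_criteria()] or preset name.
#' @return List with `counts` (integer per cell) and `summary` (data frame
#'   with `median`, `q1`, `q3`, `mean`, `sd`, `lower_2sd`, `upper_2sd`).
#' @export
clusters_per_cell <- function(tables, criteria) {
  counts <- vapply(tables,
                   function(tb) length(detect_clusters(tb, criteria)),
                   integer(1))
  q <- stats::quantile(counts, c(0.25, 0.5, 0.75), names = FALSE)
  s <- stats::sd(counts)
  if (is.na(s)) s <- 0
  list(counts = counts,
       summary = data.frame(median = q[2], q1 = q[1], q3 = q[3],
                            mean = mean(counts), sd = s,
                            lower_2sd = mean(counts) - 2 * s,
                            upper_2sd = mean(counts) + 2 * s))
}
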