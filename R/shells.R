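#' Concentric shell specification
#'
#' Geometry of the circular shells drawn around a cluster centroid for the
#' local heterochromatin density profile. Defaults: 10 shells of 50 nm
#' width, with the innermost 4 shells (out to 200 nm, the nano-cluster
#' radius scale) forming the inner region used for classification. All
#' three values are interpretations and deliberately tunable.
#'
#' @param width_nm shell width in nm.
#' @param n_shells number of shells.
#' @param inner_shells number of innermost shells forming the inner region.
#' @return An object of class `shell_spec`.
#' @export
shell_spec <- function(width_nm = 50, n_shells = 10, inner_shells = 4) {
  stopifnot(width_nm > 0, n_shells >= 1, inner_shells >= 1,
            inner_shells <= n_shells)
  structure(list(width_nm = width_nm, n_shells = as.integer(n_shells),
                 inner_shells = as.integer(inner_shells)),
            class = "shell_spec")
}

#' Heterochromatin density per concentric shell
#'
#' Number of chromatin-channel points per unit shell area, for concentric
#' non-overlapping annuli around a cluster centroid.
#'
#' @param centroid numeric length-2 centre in nm (e.g. from
#'   [cluster_centroid()]).
#' @param hc_points heterochromatin-channel localization table.
#' @param shells a [shell_spec()].
#' @return A data.frame of class `shell_density_profile` with columns
#'   `shell_lo_nm`, `shell_hi_nm`, `n_points`, `density_per_nm2`.
#' @export
shell_density_profile <- function(centroid, hc_points,
                                  shells = shell_spec()) {
  stopifnot(inherits(shells, "shell_spec"), length(centroid) == 2)
  xy <- loc_xy(hc_points)
  r <- if (nrow(xy)) sqrt((xy[, 1] - centroid[1])^2 +
                            (xy[, 2] - centroid[2])^2) else numeric()
  lo <- (seq_len(shells$n_shells) - 1) * shells$width_nm
  hi <- lo + shells$width_nm
  counts <- vapply(seq_along(lo), function(i) sum(r >= lo[i] & r < hi[i]),
                   numeric(1))
  area <- pi * (hi^2 - lo^2)
  structure(data.frame(shell_lo_nm = lo, shell_hi_nm = hi,
                       n_points = counts, density_per_nm2 = counts / area),
            class = c("shell_density_profile", "data.frame"))
}

#' Heterochromatin-association classification of cluster centres
#'
#' A cluster is heterochromatin-associated (HC) when the pooled
#' chromatin-point density over the inner shells around its centroid (the
#' disc out to `inner_shells * width_nm`) reaches the threshold density,
#' and non-associated (nHC) otherwise. The default threshold is the
#' nucleus-wide mean density of the chromatin channel, `nrow(hc_points) /
#' field_area(field)`. With an empty chromatin channel every cluster is
#' nHC.
#'
#' @param centroids numeric length-2 centre, or an n x 2 matrix /
#'   data.frame of centres (nm).
#' @param hc_points heterochromatin-channel localization table.
#' @param shells a [shell_spec()].
#' @param threshold_per_nm2 density threshold; default the nucleus-wide
#'   mean (requires `field`).
#' @param field a [field_spec()], needed for the default threshold.
#' @return Character vector of `"HC"` / `"nHC"`, one per centre.
#' @export
classify_hc_association <- function(centroids, hc_points,
                                    shells = shell_spec(),
                                    threshold_per_nm2 = NULL,
                                    field = NULL) {
  ctr <- if (is.null(dim(centroids))) matrix(centroids, 1, 2)
  else as.matrix(centroids)[, 1:2, drop = FALSE]
  n_hc <- nrow(loc_xy(hc_points))
  if (n_hc == 0) return(rep("nHC", nrow(ctr)))
  if (is.null(threshold_per_nm2)) {
    if (is.null(field))
      stop("provide `field` for the default nucleus-wide mean threshold",
           call. = FALSE)
    threshold_per_nm2 <- n_hc / field_area(field)
  }
  r_in <- shells$inner_shells * shells$width_nm
  xy <- loc_xy(hc_points)
  vapply(seq_len(nrow(ctr)), function(i) {
    d2 <- (xy[, 1] - ctr[i, 1])^2 + (xy[, 2] - ctr[i, 2])^2
    dens <- sum(d2 <= r_in^2) / (pi * r_in^2)
    if (dens >= threshold_per_nm2) "HC" else "nHC"
  }, character(1))
}

#' Label detected clusters by heterochromatin association
#'
#' Convenience wrapper: classifies every cluster in an `smlm_clusters`
#' list from its centroid and writes the label into `hc_label`.
#'
#' @param clusters an `smlm_clusters` list from [detect_clusters()].
#' @param hc_points heterochromatin-channel localization table.
#' @inheritParams classify_hc_association
#' @return The cluster list with `hc_label` filled in.
#' @export
label_clusters_hc <- function(clusters, hc_points, shells = shell_spec(),
                              threshold_per_nm2 = NULL, field = NULL) {
  if (!length(clusters)) return(clusters)
  ctr <- do.call(rbind, lapply(clusters, cluster_centroid))
  labels <- classify_hc_association(ctr, hc_points, shells,
                                    threshold_per_nm2, field)
  for (i in seq_along(clusters)) clusters[[i]]$hc_label <- labels[i]
  clusters
}
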