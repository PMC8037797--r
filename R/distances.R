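#' Ordered-pair distance frequency histogram
#'
#' Bins all pairwise point distances of a localization table into uniform
#' bins. The ordered-pair convention is used throughout: for points X and Y
#' both the X to Y and the Y to X distance are counted, so every unordered
#' pair contributes two counts and a full-range histogram sums to
#' N(N - 1). Self-distances are excluded. Bin assignment is half-open,
#' `[lo, hi)`.
#'
#' A homogeneous pattern yields a linearly growing curve at small distances
#' whose slope scales with N^2; clustered patterns add a peak at distances
#' up to the cluster diameter (see [peak_metrics()]).
#'
#' @param points a [localization_table()], data.frame or 2-column matrix.
#' @param bin_width_nm bin width in nm (> 0); the default 10 nm matches the
#'   localization precision.
#' @param d_max_nm histogram range in nm; defaults to the field diagonal
#'   when `field` is given, else to the maximum observed distance. Set it
#'   at least to the field diagonal for closed-universe analyses.
#' @param field optional [field_spec()], recorded as metadata and used for
#'   the default range.
#' @return An object of class `distance_histogram`: list with `bin_edges`
#'   (length nbins + 1), `counts` (ordered-pair counts), `n_points`,
#'   `bin_width_nm` and `field_area_nm2` (or `NA`).
#' @examples
#' pts <- localization_table(1:2, c(0, 75), c(0, 0))
#' distance_histogram(pts, bin_width_nm = 10, d_max_nm = 100)$counts
#' @export
distance_histogram <- function(points, bin_width_nm = 10, d_max_nm = NULL,
                               field = NULL) {
  if (!isTRUE(bin_width_nm > 0))
    stop("`bin_width_nm` must be > 0", call. = FALSE)
  xy <- loc_xy(points)
  n <- nrow(xy)
  d <- if (n >= 2) as.numeric(stats::dist(xy)) else numeric()
  if (is.null(d_max_nm)) {
    d_max_nm <- if (!is.null(field)) field_diagonal(field)
    else if (length(d)) max(d) else bin_width_nm
  }
  # bins cover the closed interval [0, d_max]: last edge is the smallest
  # bin-width multiple strictly above d_max (half-open assignment)
  nbins <- max(1L, as.integer(floor(d_max_nm / bin_width_nm + 1e-9)) + 1L)
  idx <- floor(d / bin_width_nm) + 1
  idx <- idx[idx <= nbins]
  counts <- 2L * tabulate(idx, nbins)
  structure(list(bin_edges = seq(0, nbins) * bin_width_nm,
                 counts = counts, n_points = n,
                 bin_width_nm = bin_width_nm,
                 field_area_nm2 = if (is.null(field)) NA_real_
                 else field_area(field)),
            class = "distance_histogram")
}

bin_centers <- function(hist) {
  (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf(
    "<distance_histogram> %d points, %d bins of %g nm, %d ordered pairs\n",
    x$n_points, length(x$counts), x$bin_width_nm, sum(x$counts)))
  invisible(x)
}

#' Slope of the linear small-distance regime
#'
#' Least-squares slope of ordered-pair counts versus bin centre over a
#' distance range. For a homogeneous pattern the counts grow linearly at
#' distances well below the field size and the slope scales with N^2.
#'
#' @param hist a [distance_histogram()].
#' @param fit_range_nm numeric length-2, distance range of the fit; keep it
#'   well below the field size (<= ~10%) to avoid boundary bias.
#' @return Slope in counts per nm.
#' @export
fit_linear_slope <- function(hist, fit_range_nm) {
  stopifnot(inherits(hist, "distance_histogram"), length(fit_range_nm) == 2)
  ctr <- bin_centers(hist)
  sel <- ctr >= fit_range_nm[1] & ctr <= fit_range_nm[2]
  if (sum(sel) < 2)
    stop("`fit_range_nm` covers fewer than two bins", call. = FALSE)
  unname(stats::coef(stats::lm(hist$counts[sel] ~ ctr[sel]))[2])
}

#' Cluster-peak metrics of a distance histogram
#'
#' Clustered patterns produce an excess of small distances over the linear
#' baseline of a homogeneous pattern. The peak is taken as the contiguous
#' run of bins, starting at the small-distance end, whose excess over the
#' baseline exceeds `threshold_k` local Poisson standard deviations of the
#' baseline. Its support width estimates the maximum intra-cluster point
#' distance (the cluster diameter, ~2R); its area estimates the number of
#' intra-cluster ordered pairs, i.e. scales with the number of clusters
#' times the squared points-per-cluster.
#'
#' @param hist a [distance_histogram()].
#' @param baseline per-bin baseline counts of the linear (homogeneous)
#'   component; a numeric vector, or `NULL` for a zero baseline
#'   (cluster-only patterns).
#' @param slope alternatively, the linear-component slope in counts per nm
#'   (e.g. from [fit_linear_slope()] of a background-only histogram); the
#'   baseline is then `slope * bin centre`.
#' @param threshold_k significance threshold in baseline Poisson standard
#'   deviations (default 3).
#' @return An object of class `peak_metrics`: list with `support_width_nm`
#'   (upper edge of the last peak bin; 0 if no peak), `area` (summed excess
#'   ordered-pair counts) and `mode_nm` (centre of the highest-excess bin,
#'   `NA` if no peak).
#' @export
peak_metrics <- function(hist, baseline = NULL, slope = NULL,
                         threshold_k = 3) {
  stopifnot(inherits(hist, "distance_histogram"))
  ctr <- bin_centers(hist)
  if (is.null(baseline)) {
    baseline <- if (is.null(slope)) rep(0, length(ctr))
    else pmax(0, slope * ctr)
  }
  if (length(baseline) != length(hist$counts))
    stop("baseline length must match the histogram", call. = FALSE)
  excess <- hist$counts - baseline
  sig <- excess > threshold_k * sqrt(baseline) & excess > 0
  # the cluster peak sits at the small-distance end: it is the contiguous
  # significant run beginning at the first bin (isolated significant bins at
  # large distances reflect cluster-centre distances, not the peak)
  if (!sig[1]) {
    return(structure(list(support_width_nm = 0, area = 0, mode_nm = NA_real_),
                     class = "peak_metrics"))
  }
  run_end <- 1L
  while (run_end < length(sig) && sig[run_end + 1]) run_end <- run_end + 1L
  run <- 1L:run_end
  structure(list(
    support_width_nm = hist$bin_edges[run_end + 1],
    area = sum(excess[run]),
    mode_nm = ctr[run][which.max(excess[run])]),
    class = "peak_metrics")
}

# chunked cross-distance histogram counts (ordered pairs: each A-B pair
# counted twice)
cross_counts <- function(xa, xb, bin_width, nbins) {
  counts <- integer(nbins)
  step <- max(1L, as.integer(2e6 / max(1, nrow(xb))))
  i <- 1L
  while (i <= nrow(xa)) {
    j <- min(nrow(xa), i + step - 1L)
    block <- xa[i:j, , drop = FALSE]
    d2 <- outer(block[, 1], xb[, 1], "-")^2 + outer(block[, 2], xb[, 2], "-")^2
    idx <- floor(sqrt(as.numeric(d2)) / bin_width) + 1
    idx <- idx[idx <= nbins]
    counts <- counts + tabulate(idx, nbins)
    i <- j + 1L
  }
  2L * counts
}

#' Two-set decomposition of a distance histogram
#'
#' Splits the ordered-pair distance histogram of the pooled set A + B into
#' the within-A part, the within-B part and the cross term holding the
#' distances between points of the two components. The decomposition is an
#' exact combinatorial identity: pooled = within_A + within_B + cross,
#' bin by bin.
#'
#' @param points_a,points_b the two point sets.
#' @param bin_width_nm common bin width in nm.
#' @param d_max_nm common histogram range; defaults to the maximum pooled
#'   distance.
#' @param field optional [field_spec()] (sets the default range).
#' @return List with `within_a`, `within_b`, `cross` and `pooled`, all
#'   [distance_histogram()] objects on the same bin grid.
#' @export
decompose_two_sets <- function(points_a, points_b, bin_width_nm = 10,
                               d_max_nm = NULL, field = NULL) {
  xa <- loc_xy(points_a)
  xb <- loc_xy(points_b)
  pooled_pts <- rbind(xa, xb)
  pooled <- distance_histogram(pooled_pts, bin_width_nm, d_max_nm, field)
  # reuse the pooled grid exactly (its last edge already covers d_max)
  d_max <- pooled$bin_edges[length(pooled$bin_edges)] - bin_width_nm / 2
  within_a <- distance_histogram(xa, bin_width_nm, d_max, field)
  within_b <- distance_histogram(xb, bin_width_nm, d_max, field)
  nbins <- length(pooled$counts)
  cross <- within_a
  cross$counts <- if (nrow(xa) && nrow(xb))
    cross_counts(xa, xb, bin_width_nm, nbins) else integer(nbins)
  cross$n_points <- nrow(pooled_pts)
  list(within_a = within_a, within_b = within_b, cross = cross,
       pooled = pooled)
}

#' Write a distance histogram as delimited text
#'
#' Columns `bin_lo,bin_hi,count`.
#' @param hist a [distance_histogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_histogram <- function(hist, path) {
  e <- hist$bin_edges
  utils::write.csv(data.frame(bin_lo = e[-length(e)], bin_hi = e[-1],
                              count = hist$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
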