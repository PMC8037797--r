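#' Cluster pattern specification
#'
#' Parameters of a simulated clustered point pattern: `n_clusters` circular
#' clusters of radius `radius_nm`, each carrying `points_per_cluster`
#' events. Cluster centres are drawn uniformly in the field so that every
#' cluster disc lies fully inside it; within a cluster, points are uniform
#' over the disc (or, optionally, an isotropic Gaussian truncated at the
#' cluster radius).
#'
#' @param n_clusters number of clusters (>= 0).
#' @param points_per_cluster events per cluster (>= 1).
#' @param radius_nm cluster radius in nm (> 0).
#' @param min_separation_nm minimum centre-to-centre distance enforced by
#'   rejection sampling; 0 (default) places centres independently.
#' @param profile within-cluster point law: `"uniform"` over the disc
#'   (default) or `"gaussian"` (sd = radius/2, truncated at the radius).
#' @return An object of class `cluster_pattern_spec`.
#' @examples
#' cluster_pattern_spec(10, 100, 50)
#' @export
cluster_pattern_spec <- function(n_clusters, points_per_cluster, radius_nm,
                                 min_separation_nm = 0,
                                 profile = c("uniform", "gaussian")) {
  profile <- match.arg(profile)
  if (n_clusters < 0) stop("`n_clusters` must be >= 0", call. = FALSE)
  if (n_clusters > 0 && points_per_cluster < 1)
    stop("`points_per_cluster` must be >= 1", call. = FALSE)
  if (!isTRUE(radius_nm > 0)) stop("`radius_nm` must be > 0", call. = FALSE)
  structure(list(n_clusters = as.integer(n_clusters),
                 points_per_cluster = as.integer(points_per_cluster),
                 radius_nm = as.numeric(radius_nm),
                 min_separation_nm = as.numeric(min_separation_nm),
                 profile = profile),
            class = "cluster_pattern_spec")
}

# uniform points in the field (vectorized; x then y)
runif_field <- function(n, field) {
  cbind(stats::runif(n, field$origin[1], field$origin[1] + field$width_nm),
        stats::runif(n, field$origin[2], field$origin[2] + field$height_nm))
}

# points within a disc around (0,0)
rdisc <- function(n, radius, profile = "uniform") {
  if (profile == "uniform") {
    r <- radius * sqrt(stats::runif(n))
  } else {
    # isotropic Gaussian, sd = radius / 2, truncated at the disc boundary
    r <- abs(stats::rnorm(n, sd = radius / 2))
    while (any(bad <- r > radius))
      r[bad] <- abs(stats::rnorm(sum(bad), sd = radius / 2))
  }
  theta <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(theta), r * sin(theta))
}

#' Simulate a homogeneous (random) point pattern
#'
#' Draws `n` events i.i.d. uniform over the field, the null model against
#' which clustered patterns are compared.
#'
#' @param n number of events (>= 0).
#' @param field a [field_spec()].
#' @param seed integer seed; the call does not touch the global RNG state.
#' @param precision_nm constant localization precision written to the
#'   precision column (default 10 nm).
#' @param channel channel identifier.
#' @return A [localization_table()] of exactly `n` events.
#' @examples
#' simulate_homogeneous(100, field_spec(24000), seed = 1)
#' @export
simulate_homogeneous <- function(n, field, seed, precision_nm = 10,
                                 channel = "A") {
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  xy <- withr::with_seed(seed, runif_field(n, field))
  localization_table(seq_len(n), xy[, 1], xy[, 2], precision_nm, channel,
                     metadata = list(field = field, seed = seed))
}

# draw cluster centres; rejection sampling for the separation constraint
draw_centers <- function(spec, field) {
  r <- spec$radius_nm
  if (2 * r > min(field$width_nm, field$height_nm))
    stop("cluster disc does not fit inside the field", call. = FALSE)
  lo <- field$origin + r
  hi <- field$origin + c(field$width_nm, field$height_nm) - r
  k <- spec$n_clusters
  centers <- matrix(NA_real_, k, 2)
  for (i in seq_len(k)) {
    for (try in seq_len(10000L)) {
      cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      if (i == 1 || spec$min_separation_nm <= 0 ||
          min(sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) -
                              cand)^2))) >= spec$min_separation_nm) {
        centers[i, ] <- cand
        break
      }
    }
    if (anyNA(centers[i, ]))
      stop("could not place cluster centres at the requested separation",
           call. = FALSE)
  }
  centers
}

simulate_clustered_impl <- function(spec, field, precision_nm, channel) {
  centers <- draw_centers(spec, field)
  k <- spec$n_clusters
  np <- spec$points_per_cluster
  labels <- rep(seq_len(k), each = np)
  if (k == 0) {
    xy <- matrix(numeric(), 0, 2)
  } else {
    off <- rdisc(k * np, spec$radius_nm, spec$profile)
    xy <- centers[labels, , drop = FALSE] + off
  }
  events <- localization_table(seq_len(nrow(xy)), xy[, 1], xy[, 2],
                               precision_nm, channel,
                               metadata = list(field = field))
  list(events = events, labels = labels, centers = centers)
}

#' Simulate a clustered point pattern
#'
#' Monte Carlo pattern of `n_clusters` circular clusters placed uniformly
#' in the field, with known ground-truth cluster labels for every event.
#'
#' @param spec a [cluster_pattern_spec()].
#' @inheritParams simulate_homogeneous
#' @return An object of class `simulated_pattern`: a list with `events`
#'   (a [localization_table()]), `labels` (integer cluster index per event;
#'   0 marks background events where present) and `centers` (matrix of
#'   cluster centres).
#' @examples
#' sim <- simulate_clustered(cluster_pattern_spec(10, 100, 50),
#'                           field_spec(24000), seed = 1)
#' table(sim$labels)
#' @export
simulate_clustered <- function(spec, field, seed, precision_nm = 10,
                               channel = "A") {
  stopifnot(inherits(spec, "cluster_pattern_spec"))
  out <- withr::with_seed(
    seed, simulate_clustered_impl(spec, field, precision_nm, channel))
  attr(out$events, "metadata")$seed <- seed
  out$spec <- spec
  out$field <- field
  out$seed <- seed
  class(out) <- "simulated_pattern"
  out
}

#' Simulate a cluster + background mixture
#'
#' Clusters as in [simulate_clustered()] plus `n_background` events uniform
#' over the field. Background events carry label 0.
#'
#' @inheritParams simulate_clustered
#' @param n_background number of homogeneous background events (>= 0).
#' @return A `simulated_pattern` (see [simulate_clustered()]).
#' @export
simulate_mixture <- function(spec, n_background, field, seed,
                             precision_nm = 10, channel = "A") {
  stopifnot(inherits(spec, "cluster_pattern_spec"))
  if (n_background < 0) stop("`n_background` must be >= 0", call. = FALSE)
  out <- withr::with_seed(seed, {
    cl <- simulate_clustered_impl(spec, field, precision_nm, channel)
    bg <- runif_field(n_background, field)
    cl$bg <- bg
    cl
  })
  xy <- rbind(loc_xy(out$events), out$bg)
  events <- localization_table(seq_len(nrow(xy)), xy[, 1], xy[, 2],
                               precision_nm, channel,
                               metadata = list(field = field, seed = seed))
  structure(list(events = events,
                 labels = c(out$labels, rep(0L, n_background)),
                 centers = out$centers, spec = spec, field = field,
                 seed = seed),
            class = "simulated_pattern")
}

#' @export
print.simulated_pattern <- function(x, ...) {
  cat(sprintf("<simulated_pattern> %d events, %d cluster(s), %d background\n",
              nrow(x$events), nrow(x$centers), sum(x$labels == 0)))
  invisible(x)
}

#' Write a simulated pattern's ground-truth labels
#'
#' @param pattern a `simulated_pattern`.
#' @param path output path for a `event_index,label` delimited file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(pattern, path) {
  utils::write.csv(
    data.frame(event_index = seq_along(pattern$labels),
               label = pattern$labels),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
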