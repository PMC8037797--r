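#' Sphere-growth (Vietoris-Rips) filtration of a point set
#'
#' Implements the sphere-contact construction: spheres of radius alpha grow
#' around every event; two points are joined by an edge as soon as their
#' spheres touch, i.e. at alpha = d(i, j) / 2, and whenever three edges
#' form a triangle its face enters the complex (at the alpha of its last
#' edge). This is the Vietoris-Rips complex at scale 2 alpha, restricted to
#' dimension <= 2, which is all that dimension-0/1 homology needs.
#'
#' Exactly duplicated points are merged with a warning (they would only
#' contribute zero-length bars). The complex has choose(n, 3) potential
#' triangles, so whole-nucleus clouds should be subsampled (see
#' [subsample_events()]) or capped with `alpha_max_nm`.
#'
#' @param points a [localization_table()], data.frame or 2-column matrix
#'   with at least one point.
#' @param alpha_max_nm optional cap: simplices entering above this alpha
#'   are omitted. Features still alive at the cap get death `Inf`.
#' @return An object of class `rips_filtration`: list with `points` (the
#'   deduplicated coordinates), `n`, `edges` (data.frame `i,j,alpha`),
#'   `triangles` (data.frame `i,j,k,alpha`) and `alpha_max_nm`.
#' @examples
#' build_filtration(rbind(c(0, 0), c(100, 0)))$edges
#' @export
build_filtration <- function(points, alpha_max_nm = Inf) {
  xy <- loc_xy(points)
  if (nrow(xy) < 1) stop("need at least one point", call. = FALSE)
  dup <- duplicated(xy)
  if (any(dup)) {
    warning(sprintf("merged %d duplicated point(s) before filtration",
                    sum(dup)))
    xy <- xy[!dup, , drop = FALSE]
  }
  n <- nrow(xy)
  edges <- data.frame(i = integer(), j = integer(), alpha = numeric())
  triangles <- data.frame(i = integer(), j = integer(), k = integer(),
                          alpha = numeric())
  if (n >= 2) {
    D <- as.matrix(stats::dist(xy))
    ut <- which(upper.tri(D) & D / 2 <= alpha_max_nm, arr.ind = TRUE)
    edges <- data.frame(i = ut[, 1], j = ut[, 2],
                        alpha = D[ut] / 2)
    edges <- edges[order(edges$alpha, edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
    if (n >= 3 && nrow(edges) >= 3) {
      # adjacency (under the cap) for triangle enumeration
      adj <- lapply(seq_len(n), function(i) {
        cand <- which(D[i, ] / 2 <= alpha_max_nm)
        cand[cand > i]
      })
      ti <- tj <- tk <- ta <- list()
      m <- 0L
      for (i in seq_len(n)) {
        for (j in adj[[i]]) {
          ks <- intersect(adj[[i]], adj[[j]])
          if (length(ks)) {
            m <- m + 1L
            ti[[m]] <- rep.int(i, length(ks))
            tj[[m]] <- rep.int(j, length(ks))
            tk[[m]] <- ks
            ta[[m]] <- pmax(D[i, j], pmax(D[i, ks], D[j, ks])) / 2
          }
        }
      }
      if (m) {
        triangles <- data.frame(i = unlist(ti), j = unlist(tj),
                                k = unlist(tk), alpha = unlist(ta))
        triangles <- triangles[order(triangles$alpha, triangles$i,
                                     triangles$j, triangles$k), ,
                               drop = FALSE]
        rownames(triangles) <- NULL
      }
    }
  }
  structure(list(points = xy, n = n, edges = edges, triangles = triangles,
                 alpha_max_nm = alpha_max_nm),
            class = "rips_filtration")
}

#' @export
print.rips_filtration <- function(x, ...) {
  cat(sprintf(
    "<rips_filtration> %d vertices, %d edges, %d triangles (alpha_max %s)\n",
    x$n, nrow(x$edges), nrow(x$triangles),
    if (is.finite(x$alpha_max_nm)) paste0(x$alpha_max_nm, " nm") else "Inf"))
  invisible(x)
}

#' Persistence barcode of a filtration
#'
#' Dimension-0 bars (connected components) are computed by union-find over
#' the edge insertions: every merge kills one component at the edge's
#' alpha, and each surviving component contributes one infinite bar (a
#' connected point set has exactly one). Dimension-1 bars (holes) are
#' obtained by GF(2) boundary-matrix reduction of the triangle columns
#' against the cycle-creating edges: a hole is born at the alpha of the
#' edge that closes the cycle and dies at the alpha of the triangle that
#' fills it.
#'
#' @param x a `rips_filtration` from [build_filtration()], or a point set
#'   (coerced with [build_filtration()]).
#' @param alpha_max_nm passed to [build_filtration()] when `x` is a point
#'   set.
#' @param keep_zero keep bars with birth exactly equal to death
#'   (default `FALSE`).
#' @return An object of class `persistence_barcode`: a data.frame with
#'   columns `dimension` (0 or 1), `birth` and `death` (alpha in nm, `Inf`
#'   for essential bars), and attributes `n_points`, `unit` (`"nm"`) and
#'   `scale_reference` (the largest finite death, used for scale
#'   normalization in similarity comparisons).
#' @examples
#' bc <- persistence_barcode(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' bc[bc$dimension == 1, ]  # one hole: [0.5, sqrt(2)/2]
#' @export
persistence_barcode <- function(x, alpha_max_nm = Inf, keep_zero = FALSE) {
  filt <- if (inherits(x, "rips_filtration")) x
  else build_filtration(x, alpha_max_nm)
  n <- filt$n
  ne <- nrow(filt$edges)

  parent <- seq_len(n)
  uf_find <- function(i) {   # union-find with path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  deaths0 <- numeric()
  positive_edge <- logical(ne)
  for (e in seq_len(ne)) {
    ri <- uf_find(filt$edges$i[e])
    rj <- uf_find(filt$edges$j[e])
    if (ri == rj) {
      positive_edge[e] <- TRUE
    } else {
      parent[ri] <- rj
      deaths0 <- c(deaths0, filt$edges$alpha[e])
    }
  }
  n_components <- n - length(deaths0)
  bars <- data.frame(
    dimension = 0L,
    birth = rep(0, length(deaths0) + n_components),
    death = c(deaths0, rep(Inf, n_components)))

  nt <- nrow(filt$triangles)
  if (nt > 0) {
    # edge rank lookup by encoded pair key (vectorized, O(1) per access)
    key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
    lookup <- integer(n * n)
    lookup[key(filt$edges$i, filt$edges$j)] <- seq_len(ne)
    r1 <- lookup[key(filt$triangles$i, filt$triangles$j)]
    r2 <- lookup[key(filt$triangles$i, filt$triangles$k)]
    r3 <- lookup[key(filt$triangles$j, filt$triangles$k)]
    pairs <- reduce_triangle_columns(cbind(r1, r2, r3), ne)
    b1 <- filt$edges$alpha[pairs$edge]
    d1 <- filt$triangles$alpha[pairs$triangle]
    # positive edges never killed by a triangle: essential holes (possible
    # only under an alpha_max cap)
    paired_edges <- logical(ne)
    paired_edges[pairs$edge] <- TRUE
    unpaired <- which(positive_edge & !paired_edges)
    if (length(b1) || length(unpaired)) {
      bars <- rbind(bars, data.frame(
        dimension = 1L,
        birth = c(b1, filt$edges$alpha[unpaired]),
        death = c(d1, rep(Inf, length(unpaired)))))
    }
  } else if (any(positive_edge)) {
    bars <- rbind(bars, data.frame(
      dimension = 1L,
      birth = filt$edges$alpha[positive_edge],
      death = Inf))
  }

  if (!keep_zero) bars <- bars[bars$birth != bars$death, , drop = FALSE]
  bars <- bars[order(bars$dimension, bars$birth, bars$death), , drop = FALSE]
  rownames(bars) <- NULL
  new_barcode(bars, n_points = n, unit = "nm")
}

new_barcode <- function(bars, n_points, unit) {
  finite <- bars$death[is.finite(bars$death)]
  structure(bars, n_points = n_points, unit = unit,
            scale_reference = if (length(finite)) max(finite) else NA_real_,
            class = c("persistence_barcode", "data.frame"))
}

#' @export
print.persistence_barcode <- function(x, ...) {
  cat(sprintf(
    "<persistence_barcode> %d points, %d dim-0 and %d dim-1 bars (%s)\n",
    attr(x, "n_points"), sum(x$dimension == 0), sum(x$dimension == 1),
    attr(x, "unit")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Betti numbers at a fixed filtration radius
#'
#' Counts the bars alive at radius `alpha`: a bar `[birth, death)` is alive
#' when `birth <= alpha < death`.
#'
#' @param x a `persistence_barcode` or `rips_filtration` (a point set is
#'   also accepted).
#' @param alpha radius, in the barcode's unit (nm unless converted).
#' @return Named integer vector `c(B0 = ..., B1 = ...)`.
#' @export
betti_numbers <- function(x, alpha) {
  stopifnot(alpha >= 0)
  bc <- if (inherits(x, "persistence_barcode")) x
  else persistence_barcode(x, keep_zero = TRUE)
  alive <- bc$birth <= alpha & alpha < bc$death
  c(B0 = sum(alive & bc$dimension == 0L),
    B1 = sum(alive & bc$dimension == 1L))
}

#' Round barcode endpoints and prune degenerate bars
#'
#' Births and deaths are expressed in the requested unit (micrometres by
#' default, so two decimals correspond to a 10-nm granularity on the
#' radius scale), rounded to `decimals` places, and bars whose rounded
#' birth equals their rounded death are excluded.
#'
#' @param barcode a `persistence_barcode`.
#' @param decimals decimal places (default 2).
#' @param unit output unit, `"um"` (default) or `"nm"`.
#' @return A rounded, pruned `persistence_barcode` in the requested unit.
#' @export
round_and_prune <- function(barcode, decimals = 2, unit = c("um", "nm")) {
  unit <- match.arg(unit)
  stopifnot(inherits(barcode, "persistence_barcode"))
  from <- attr(barcode, "unit")
  f <- if (from == "nm" && unit == "um") 1e-3
  else if (from == "um" && unit == "nm") 1e3 else 1
  bars <- as.data.frame(barcode)
  bars$birth <- round(bars$birth * f, decimals)
  bars$death <- round(bars$death * f, decimals)
  bars <- bars[!(is.finite(bars$death) & bars$birth == bars$death), ,
               drop = FALSE]
  rownames(bars) <- NULL
  new_barcode(bars, n_points = attr(barcode, "n_points"), unit = unit)
}

#' Uniform subsampling of events
#'
#' Utility for capping the size of point clouds ahead of the persistence
#' computation.
#'
#' @param points a [localization_table()] (or data.frame).
#' @param n maximum number of events to keep.
#' @param seed integer seed.
#' @return The table restricted to a uniform random subset of `n` rows
#'   (unchanged when it has at most `n`).
#' @export
subsample_events <- function(points, n, seed) {
  if (nrow(points) <= n) return(points)
  keep <- withr::with_seed(seed, sort(sample.int(nrow(points), n)))
  points[keep, , drop = FALSE]
}

#' Normalized bar-endpoint histograms averaged across nuclei
#'
#' For each nucleus (barcode) and dimension, the histogram of the bar
#' endpoints (death values, the highest alpha of each bar; infinite bars
#' excluded) is normalized to sum 1 and the per-nucleus histograms are then
#' averaged without weighting. The endpoint distribution of dimension 0
#' reflects the separation of sub-components, that of dimension 1 the size
#' of the holes.
#'
#' @param barcodes list of `persistence_barcode` objects, one per nucleus,
#'   all in the same unit.
#' @param bin_width bin width in the barcodes' unit (default 0.05, i.e.
#'   0.05 um for micrometre barcodes).
#' @param bin_edges optional explicit bin edges (overrides `bin_width`).
#' @return An object of class `endpoint_histogram`: list with `bin_edges`,
#'   `freq_dim0`, `freq_dim1` (each summing to 1), `n_nuclei_dim0`,
#'   `n_nuclei_dim1` (nuclei contributing; a nucleus with no finite bar in
#'   a dimension is skipped for that dimension, with a message) and `unit`.
#' @export
endpoint_histogram <- function(barcodes, bin_width = 0.05,
                               bin_edges = NULL) {
  stopifnot(length(barcodes) >= 1)
  units <- vapply(barcodes, attr, character(1), "unit")
  if (length(unique(units)) != 1)
    stop("barcodes must share one unit", call. = FALSE)
  all_deaths <- unlist(lapply(barcodes, function(b)
    b$death[is.finite(b$death)]))
  if (!length(all_deaths))
    stop("no finite bars in any barcode", call. = FALSE)
  if (is.null(bin_edges)) {
    hi <- max(all_deaths)
    bin_edges <- seq(0, bin_width * max(1, ceiling(hi / bin_width + 1e-12)),
                     by = bin_width)
  }
  nb <- length(bin_edges) - 1
  avg <- function(dimension) {
    hs <- list()
    for (i in seq_along(barcodes)) {
      b <- barcodes[[i]]
      deaths <- b$death[b$dimension == dimension & is.finite(b$death)]
      if (!length(deaths)) {
        message(sprintf("nucleus %d has no finite dimension-%d bars; skipped",
                        i, dimension))
        next
      }
      idx <- findInterval(deaths, bin_edges, rightmost.closed = TRUE)
      idx <- idx[idx >= 1 & idx <= nb]
      h <- tabulate(idx, nb)
      hs[[length(hs) + 1]] <- h / sum(h)
    }
    if (!length(hs)) return(list(freq = rep(NA_real_, nb), n = 0L))
    list(freq = Reduce(`+`, hs) / length(hs), n = length(hs))
  }
  h0 <- avg(0L)
  h1 <- avg(1L)
  structure(list(bin_edges = bin_edges, freq_dim0 = h0$freq,
                 freq_dim1 = h1$freq, n_nuclei_dim0 = h0$n,
                 n_nuclei_dim1 = h1$n, unit = units[1]),
            class = "endpoint_histogram")
}

#' @export
print.endpoint_histogram <- function(x, ...) {
  cat(sprintf(
    "<endpoint_histogram> %d bins (%s), %d/%d nuclei (dim0/dim1)\n",
    length(x$bin_edges) - 1, x$unit, x$n_nuclei_dim0, x$n_nuclei_dim1))
  invisible(x)
}
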