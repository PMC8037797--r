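#' Jaccard similarity of two barcode bars
#'
#' Intersection length over union length of the two intervals
#' `[birth, death]`. The value lies in `[0, 1]`: 0 means no overlap, 1
#' means the two bars are identical. Two identical degenerate
#' (zero-length) bars have an empty union and are defined to be identical
#' (similarity 1).
#'
#' @param bar_a,bar_b numeric length-2 `c(birth, death)` vectors (or
#'   one-row pieces of a `persistence_barcode`); must be finite.
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaccard_interval(c(0, 2), c(1, 3))  # 1/3
#' @export
jaccard_interval <- function(bar_a, bar_b) {
  a <- as_interval(bar_a)
  b <- as_interval(bar_b)
  inter <- min(a[2], b[2]) - max(a[1], b[1])
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni == 0) return(1)  # two identical degenerate bars
  max(0, inter) / uni
}

as_interval <- function(bar) {
  v <- if (is.data.frame(bar)) c(bar$birth[1], bar$death[1])
  else as.numeric(bar)[1:2]
  if (any(!is.finite(v))) stop("bars must be finite", call. = FALSE)
  if (v[2] < v[1]) stop("death must be >= birth", call. = FALSE)
  v
}

# finite bars of one dimension as a 2-column matrix, optionally normalized
# by the barcode's scale reference
finite_bars <- function(bc, dimension, normalize) {
  b <- bc[bc$dimension == dimension & is.finite(bc$death), , drop = FALSE]
  m <- cbind(b$birth, b$death)
  if (normalize && nrow(m)) {
    s <- attr(bc, "scale_reference")
    if (is.na(s) || s <= 0) s <- 1
    m <- m / s
  }
  m
}

# maximum-weight one-to-one matching value for a non-negative weight matrix
match_weight <- function(w) {
  keep <- which(w > 0, arr.ind = TRUE)
  if (!nrow(keep)) return(0)
  na <- nrow(w)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, na), rep(TRUE, ncol(w))),
    edges = as.vector(t(cbind(keep[, 1], na + keep[, 2]))))
  igraph::max_bipartite_match(g, weights = w[keep])$matching_weight
}

#' Barcode similarity in one dimension
#'
#' Matches the bars of the two barcodes one-to-one so that the summed
#' interval-Jaccard similarity is maximal (maximum-weight bipartite
#' assignment) and reports the total divided by the larger bar count, so
#' unmatched bars penalize. With `method = "best_match"` the assignment is
#' replaced by the mean of each bar's best match, averaged over both
#' directions. Before comparison the bar endpoints of each barcode are
#' divided by its scale reference (largest finite death) so that the
#' comparison is independent of the object's scale; disable with
#' `normalize = FALSE`.
#'
#' Infinite bars are excluded. If both barcodes are empty in the dimension
#' the similarity is 1 (identical emptiness, reported with a message); if
#' only one is empty it is 0.
#'
#' @param bc_a,bc_b `persistence_barcode` objects (rounded/pruned barcodes
#'   recommended, see [round_and_prune()]).
#' @param dimension 0 (components) or 1 (holes).
#' @param normalize divide endpoints by each barcode's scale reference.
#' @param method `"assignment"` (default) or `"best_match"`.
#' @return Similarity in `[0, 1]`.
#' @export
barcode_similarity <- function(bc_a, bc_b, dimension,
                               normalize = TRUE,
                               method = c("assignment", "best_match")) {
  method <- match.arg(method)
  a <- finite_bars(bc_a, dimension, normalize)
  b <- finite_bars(bc_b, dimension, normalize)
  if (nrow(a) == 0 && nrow(b) == 0) {
    message(sprintf("both barcodes empty in dimension %d: similarity 1",
                    dimension))
    return(1)
  }
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  w <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      w[i, j] <- jaccard_interval(a[i, ], b[j, ])
  if (method == "assignment") {
    match_weight(w) / max(nrow(a), nrow(b))
  } else {
    (sum(apply(w, 1, max)) + sum(apply(w, 2, max))) / (nrow(a) + nrow(b))
  }
}

#' Overall barcode similarity
#'
#' Arithmetic mean of the dimension-0 (components) and dimension-1 (holes)
#' barcode similarities.
#'
#' @inheritParams barcode_similarity
#' @param ... passed on to [barcode_similarity()].
#' @return Similarity in `[0, 1]`.
#' @export
overall_similarity <- function(bc_a, bc_b, ...) {
  (barcode_similarity(bc_a, bc_b, 0L, ...) +
     barcode_similarity(bc_a, bc_b, 1L, ...)) / 2
}

#' All-versus-all similarity heatmap matrix
#'
#' Computes the symmetric matrix of pairwise cluster similarities, with the
#' heterochromatin-associated (HC) clusters ordered first and the
#' non-associated (nHC) ones after, so the upper-left block compares HC
#' with HC and the lower-right block nHC with nHC. For the topology
#' measures (`dim0`, `dim1`, `overall`) the diagonal is 1 (every cluster is
#' topologically identical to itself). For `measure = "size"` the entry is
#' the absolute difference of the cluster sizes (small difference = great
#' similarity; not bounded by 1).
#'
#' @param barcodes list of `persistence_barcode` objects, one per cluster.
#' @param hc_labels character vector, `"HC"` or `"nHC"` per cluster.
#' @param measure `"overall"`, `"dim0"`, `"dim1"` or `"size"`.
#' @param sizes numeric cluster sizes (e.g. RMS size in nm), required for
#'   `measure = "size"`.
#' @param ids optional cluster identifiers (default sequence).
#' @param ... passed to [barcode_similarity()].
#' @return An object of class `similarity_matrix`: list with `values`
#'   (symmetric matrix), `labels` (data.frame `id`, `hc_label` in matrix
#'   order) and `measure`.
#' @export
similarity_heatmap <- function(barcodes, hc_labels,
                               measure = c("overall", "dim0", "dim1",
                                           "size"),
                               sizes = NULL, ids = NULL, ...) {
  measure <- match.arg(measure)
  n <- length(hc_labels)
  if (measure != "size" && length(barcodes) != n)
    stop("one barcode per label required", call. = FALSE)
  if (measure == "size" && (is.null(sizes) || length(sizes) != n))
    stop("`sizes` required for measure = \"size\"", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(n)
  ord <- order(factor(hc_labels, levels = c("HC", "nHC")))
  if (n == 0) {
    return(structure(list(values = matrix(numeric(), 0, 0),
                          labels = data.frame(id = character(),
                                              hc_label = character()),
                          measure = measure),
                     class = "similarity_matrix"))
  }
  values <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      oi <- ord[i]; oj <- ord[j]
      v <- if (measure == "size") abs(sizes[oi] - sizes[oj])
      else if (i == j) 1
      else switch(measure,
                  overall = overall_similarity(barcodes[[oi]],
                                               barcodes[[oj]], ...),
                  dim0 = barcode_similarity(barcodes[[oi]], barcodes[[oj]],
                                            0L, ...),
                  dim1 = barcode_similarity(barcodes[[oi]], barcodes[[oj]],
                                            1L, ...))
      values[i, j] <- values[j, i] <- v
    }
  }
  structure(list(values = values,
                 labels = data.frame(id = ids[ord],
                                     hc_label = hc_labels[ord],
                                     stringsAsFactors = FALSE),
                 measure = measure),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d (%s), %d HC / %d nHC\n",
              nrow(x$values), ncol(x$values), x$measure,
              sum(x$labels$hc_label == "HC"),
              sum(x$labels$hc_label == "nHC")))
  invisible(x)
}

#' Block summary of a similarity matrix
#'
#' Mean similarity within the HC block, within the nHC block and across
#' the two, excluding the self-comparison diagonal.
#'
#' @param matrix a `similarity_matrix`.
#' @return Named numeric vector `c(hc_hc, nhc_nhc, hc_nhc)`.
#' @export
block_summary <- function(matrix) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  hc <- which(matrix$labels$hc_label == "HC")
  nhc <- which(matrix$labels$hc_label == "nHC")
  m <- matrix$values
  off_mean <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    sub <- m[idx, idx, drop = FALSE]
    mean(sub[row(sub) != col(sub)])
  }
  c(hc_hc = off_mean(hc), nhc_nhc = off_mean(nhc),
    hc_nhc = if (length(hc) && length(nhc))
      mean(m[hc, nhc, drop = FALSE]) else NA_real_)
}

#' Second-generation heatmap: condition-averaged block summaries
#'
#' Reduces each first-generation similarity matrix to its block summary
#' (mean HC-HC, nHC-nHC and HC-nHC similarity) and averages the summaries
#' within each condition, visualizing nanostructure topological changes
#' across conditions.
#'
#' @param matrices list of `similarity_matrix` objects.
#' @param conditions vector (one per matrix) grouping the matrices;
#'   a single condition is assumed when omitted.
#' @return A data.frame with one row per condition and columns `condition`,
#'   `hc_hc`, `nhc_nhc`, `hc_nhc` and `n_matrices`.
#' @export
second_generation_heatmap <- function(matrices, conditions = NULL) {
  if (is.null(conditions)) conditions <- rep("all", length(matrices))
  if (length(conditions) != length(matrices))
    stop("one condition per matrix required", call. = FALSE)
  sums <- t(vapply(matrices, block_summary, numeric(3)))
  out <- do.call(rbind, lapply(split(seq_along(matrices), conditions),
                               function(idx) {
    data.frame(condition = conditions[idx[1]],
               hc_hc = mean(sums[idx, "hc_hc"]),
               nhc_nhc = mean(sums[idx, "nhc_nhc"]),
               hc_nhc = mean(sums[idx, "hc_nhc"]),
               n_matrices = length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a similarity matrix as labeled delimited text
#'
#' First two columns carry the cluster id and HC label; the header row
#' repeats the ids.
#'
#' @param matrix a `similarity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(matrix, path) {
  df <- data.frame(id = matrix$labels$id, hc_label = matrix$labels$hc_label,
                   matrix$values, stringsAsFactors = FALSE)
  names(df) <- c("id", "hc_label", paste0("c", matrix$labels$id))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
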