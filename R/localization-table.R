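#' Localization tables
#'
#' A localization table is the coordinate matrix produced by SMLM
#' acquisition: one row per blink event with the camera frame index, the
#' fitted position in nm, the localization precision in nm and a channel
#' identifier. It is a plain `data.frame` subclass so that all the usual
#' data-frame tooling applies.
#'
#' @param frame integer frame indices (recycled).
#' @param x_nm,y_nm numeric event coordinates in nm; must be finite.
#' @param precision_nm numeric localization precision in nm, strictly
#'   positive (recycled; default 10 nm, the instrument-scale precision).
#' @param channel channel identifier (recycled; default `"A"`).
#' @param metadata optional named list of per-table metadata (nucleus id,
#'   field specification, ...), stored as an attribute.
#'
#' @return An object of class `localization_table` (also a `data.frame`)
#'   with columns `frame`, `x_nm`, `y_nm`, `precision_nm`, `channel`.
#' @examples
#' localization_table(1:3, x_nm = c(0, 50, 100), y_nm = c(0, 0, 0))
#' @export
localization_table <- function(frame = integer(), x_nm = numeric(),
                               y_nm = numeric(), precision_nm = 10,
                               channel = "A", metadata = list()) {
  n <- length(x_nm)
  if (length(y_nm) != n)
    stop("`x_nm` and `y_nm` must have the same length", call. = FALSE)
  df <- data.frame(
    frame = rep_len(as.integer(frame), n),
    x_nm = as.numeric(x_nm),
    y_nm = as.numeric(y_nm),
    precision_nm = rep_len(as.numeric(precision_nm), n),
    channel = rep_len(as.character(channel), n),
    stringsAsFactors = FALSE
  )
  if (n == 0) {
    df <- data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
                     precision_nm = numeric(), channel = character(),
                     stringsAsFactors = FALSE)
  }
  validate_localization_table(df)
  structure(df, metadata = metadata,
            class = c("localization_table", "data.frame"))
}

validate_localization_table <- function(df) {
  if (nrow(df)) {
    if (!all(is.finite(df$x_nm)) || !all(is.finite(df$y_nm)))
      stop("coordinates must be finite", call. = FALSE)
    if (!all(df$precision_nm > 0))
      stop("`precision_nm` must be > 0", call. = FALSE)
  }
  invisible(df)
}

#' Coerce to a localization table
#'
#' @param x a `data.frame` with at least `x_nm` and `y_nm` columns, a
#'   two-column numeric matrix, or an existing `localization_table`.
#' @param ... passed to [localization_table()] for missing columns.
#' @return A `localization_table`.
#' @export
as_localization_table <- function(x, ...) {
  if (inherits(x, "localization_table")) return(x)
  if (is.matrix(x)) {
    return(localization_table(seq_len(nrow(x)), x[, 1], x[, 2], ...))
  }
  if (is.data.frame(x)) {
    if (!all(c("x_nm", "y_nm") %in% names(x)))
      stop("need `x_nm` and `y_nm` columns", call. = FALSE)
    return(localization_table(
      frame = if ("frame" %in% names(x)) x$frame else seq_len(nrow(x)),
      x_nm = x$x_nm, y_nm = x$y_nm,
      precision_nm = if ("precision_nm" %in% names(x)) x$precision_nm else 10,
      channel = if ("channel" %in% names(x)) x$channel else "A"
    ))
  }
  stop("cannot coerce to localization_table", call. = FALSE)
}

# internal: n x 2 coordinate matrix from anything point-like
loc_xy <- function(points) {
  if (inherits(points, "localization_table") || is.data.frame(points)) {
    cbind(points$x_nm, points$y_nm)
  } else if (is.matrix(points)) {
    points[, 1:2, drop = FALSE]
  } else {
    stop("expected a localization table, data.frame or matrix", call. = FALSE)
  }
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("<localization_table> %d events, %d channel(s)\n",
              nrow(x), length(unique(x$channel))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
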