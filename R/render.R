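#' Pointillist rendering of localization data
#'
#' Renders a localization table onto a raster canvas. Three modes:
#' `"dot"` lights the pixel under every event; `"density"` scales each
#' event's intensity by its k-nearest-neighbour point density, so clustered
#' signals appear brighter than isolated ones; `"gaussian"` splats each
#' event with an isotropic Gaussian of its localization precision.
#'
#' @param points a [localization_table()].
#' @param field a [field_spec()] mapping nm to the canvas (defaults to the
#'   table's field metadata, else the bounding box).
#' @param width_px,height_px canvas size in pixels.
#' @param mode `"dot"`, `"density"` or `"gaussian"`.
#' @param k neighbours for the density mode.
#' @param path optional PNG output path (requires the `png` package).
#' @return A `height_px` x `width_px` intensity matrix in `[0, 1]` (row 1 =
#'   top of the image), invisibly when `path` is given. An empty table
#'   yields a blank canvas with a warning.
#' @export
render_pointillist <- function(points, field = NULL, width_px = 512,
                               height_px = 512,
                               mode = c("dot", "density", "gaussian"),
                               k = 10, path = NULL) {
  mode <- match.arg(mode)
  img <- matrix(0, height_px, width_px)
  xy <- loc_xy(points)
  if (nrow(xy) == 0) {
    warning("empty localization table: blank canvas")
  } else {
    if (is.null(field)) field <- attr(points, "metadata")$field
    if (is.null(field)) {
      pad <- 1
      field <- field_spec(diff(range(xy[, 1])) + 2 * pad,
                          diff(range(xy[, 2])) + 2 * pad,
                          origin = c(min(xy[, 1]) - pad, min(xy[, 2]) - pad))
    }
    px <- pmin(width_px, pmax(1, ceiling(
      (xy[, 1] - field$origin[1]) / field$width_nm * width_px)))
    py <- pmin(height_px, pmax(1, ceiling(
      (xy[, 2] - field$origin[2]) / field$height_nm * height_px)))
    row <- height_px - py + 1  # y increases upward, row 1 on top
    if (mode == "dot") {
      img[cbind(row, px)] <- 1
    } else if (mode == "density") {
      kk <- min(k, nrow(xy) - 1)
      dens <- if (kk < 1) rep(1, nrow(xy)) else {
        D <- as.matrix(stats::dist(xy))
        rk <- apply(D, 1, function(d) sort(d)[kk + 1])
        kk / (pi * rk^2)
      }
      for (i in seq_len(nrow(xy)))
        img[row[i], px[i]] <- max(img[row[i], px[i]], dens[i])
      if (max(img) > 0) img <- img / max(img)
    } else {
      sx <- points$precision_nm / field$width_nm * width_px
      reach <- pmax(1, ceiling(3 * sx))
      for (i in seq_len(nrow(xy))) {
        cs <- max(1, px[i] - reach[i]):min(width_px, px[i] + reach[i])
        rs <- max(1, row[i] - reach[i]):min(height_px, row[i] + reach[i])
        g <- exp(-(outer((rs - row[i])^2, (cs - px[i])^2, "+")) /
                   (2 * sx[i]^2))
        img[rs, cs] <- img[rs, cs] + g
      }
      if (max(img) > 0) img <- img / max(img)
    }
  }
  if (!is.null(path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the `png` package is required to write PNG files",
           call. = FALSE)
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}
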