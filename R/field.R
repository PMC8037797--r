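#' Rectangular analysis field
#'
#' The rectangular region in which point patterns are simulated or
#' analysed ("quadratic area analyzed"), in nm.
#'
#' @param width_nm,height_nm field extent in nm; must be > 0.
#' @param origin numeric length-2, lower-left corner in nm (y increases
#'   upward).
#' @return An object of class `field_spec`.
#' @examples
#' field_spec(24000, 24000)
#' @export
field_spec <- function(width_nm, height_nm = width_nm, origin = c(0, 0)) {
  stopifnot(length(origin) == 2)
  if (!isTRUE(width_nm > 0) || !isTRUE(height_nm > 0))
    stop("field width and height must be > 0", call. = FALSE)
  structure(list(width_nm = as.numeric(width_nm),
                 height_nm = as.numeric(height_nm),
                 origin = as.numeric(origin)),
            class = "field_spec")
}

#' @rdname field_spec
#' @param field a `field_spec`.
#' @export
field_area <- function(field) field$width_nm * field$height_nm

#' @rdname field_spec
#' @export
field_diagonal <- function(field) sqrt(field$width_nm^2 + field$height_nm^2)

# internal: are points inside the field (closed rectangle)?
in_field <- function(x, y, field) {
  x >= field$origin[1] & x <= field$origin[1] + field$width_nm &
    y >= field$origin[2] & y <= field$origin[2] + field$height_nm
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> %g x %g nm, origin (%g, %g)\n",
              x$width_nm, x$height_nm, x$origin[1], x$origin[2]))
  invisible(x)
}
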