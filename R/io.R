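#' Read a localization table from delimited text
#'
#' Reads comma- or tab-delimited SMLM export files with a mandatory header.
#' Lines starting with `#` are comments. Required columns are `frame`,
#' `x_nm`, `y_nm`, `precision_nm` and `channel`; other naming conventions
#' can be mapped with `column_map`. Unknown extra columns are preserved in
#' the `extra_columns` metadata entry.
#'
#' @param path input file.
#' @param delim field delimiter; `NULL` (default) sniffs comma vs tab from
#'   the header line.
#' @param column_map named character vector mapping required names to the
#'   file's column names, e.g. `c(x_nm = "x [nm]")`.
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, delim = NULL, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no header line in ", path, call. = FALSE)
  if (is.null(delim))
    delim <- if (grepl("\t", lines[1])) "\t" else ","
  raw <- utils::read.table(text = lines, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("frame", "x_nm", "y_nm", "precision_nm", "channel")
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      if (column_map[[std]] %in% names(raw))
        names(raw)[names(raw) == column_map[[std]]] <- std
    }
  }
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric `%s` value on line %d of %s", col,
                   line_no[bad[1] + 1L], path), call. = FALSE)
    v
  }
  extra <- raw[setdiff(names(raw), required)]
  localization_table(
    frame = as.integer(num("frame")), x_nm = num("x_nm"), y_nm = num("y_nm"),
    precision_nm = if (nrow(raw)) num("precision_nm") else numeric(),
    channel = raw$channel,
    metadata = list(source = path,
                    extra_columns = if (ncol(extra)) extra else NULL))
}

#' Write a localization table as delimited text
#'
#' Comma-delimited with the columns `frame,x_nm,y_nm,precision_nm,channel`
#' and a comment header stating the coordinate convention (nm, origin at
#' the field corner, y increasing upward).
#'
#' @param table a [localization_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates in nm; origin at field corner; y increases upward",
             con)
  utils::write.table(as.data.frame(table)[
    c("frame", "x_nm", "y_nm", "precision_nm", "channel")],
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Barcode text export / import
#'
#' Delimited text with columns `dimension,birth,death`; infinite deaths are
#' written as `inf`.
#'
#' @param barcode a `persistence_barcode`.
#' @param path file path.
#' @return `write_barcode()`: `path`, invisibly. `read_barcode()`: a
#'   `persistence_barcode` (unit taken from the file's comment header).
#' @export
write_barcode <- function(barcode, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit: %s; n_points: %d", attr(barcode, "unit"),
                     attr(barcode, "n_points")), con)
  df <- as.data.frame(barcode)
  df$death <- ifelse(is.finite(df$death), format(df$death, digits = 15),
                     "inf")
  df$birth <- format(df$birth, digits = 15)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_barcode
#' @export
read_barcode <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  unit <- sub(".*unit: (\\w+).*", "\\1", meta[1])
  n_points <- as.integer(sub(".*n_points: (\\d+).*", "\\1", meta[1]))
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE,
                        colClasses = c("integer", "numeric", "character"))
  df$death <- ifelse(df$death == "inf", Inf, suppressWarnings(
    as.numeric(df$death)))
  new_barcode(df, n_points = n_points, unit = unit)
}

#' Write an endpoint histogram as delimited text
#'
#' Columns `bin_lo,bin_hi,freq_dim0,freq_dim1`.
#'
#' @param hist an [endpoint_histogram()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_endpoint_histogram <- function(hist, path) {
  e <- hist$bin_edges
  utils::write.csv(data.frame(bin_lo = e[-length(e)], bin_hi = e[-1],
                              freq_dim0 = hist$freq_dim0,
                              freq_dim1 = hist$freq_dim1),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
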