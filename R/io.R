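#' Read a 2D point set from a delimited text file
#'
#' Reads CSV or TSV files of x,y coordinates. Row order is preserved: the
#' point index used in all outputs is the data row number (1-based,
#' header excluded). Coordinates may be integers or reals.
#'
#' @param path File path.
#' @param format `"auto"` (by extension / sniffing), `"csv"` or `"tsv"`.
#' @param header `"auto"` or logical.
#' @param x_col,y_col Coordinate columns, by name or position. `NULL`
#'   picks columns named `x` and `y` when present, else columns 1 and 2.
#' @return A point matrix (see [as_points()]).
#' @export
read_points <- function(path, format = c("auto", "csv", "tsv"),
                        header = "auto", x_col = NULL, y_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- switch(format, auto = "auto", csv = ",", tsv = "\t")
  dt <- data.table::fread(path, sep = sep, header = header,
                          data.table = FALSE, colClasses = "character")
  if (ncol(dt) < 2L) stop("need at least two columns in ", path)
  resolve <- function(col, default_name, default_pos) {
    if (is.null(col)) {
      if (default_name %in% names(dt)) default_name else default_pos
    } else if (is.character(col)) {
      if (!col %in% names(dt)) stop("no column `", col, "` in ", path)
      col
    } else {
      col <- as.integer(col)
      if (is.na(col) || col < 1L || col > ncol(dt))
        stop("column position ", col, " out of range in ", path)
      col
    }
  }
  xc <- dt[[resolve(x_col, "x", 1L)]]
  yc <- dt[[resolve(y_col, "y", 2L)]]
  x <- suppressWarnings(as.numeric(xc))
  y <- suppressWarnings(as.numeric(yc))
  bad <- which((is.na(x) & !is.na(xc)) | (is.na(y) & !is.na(yc)) |
                 is.na(xc) | is.na(yc))
  if (length(bad))
    stop("non-numeric coordinate at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), " of ", path)
  as_points(cbind(x = x, y = y))
}

#' Write a point set to CSV at full precision
#'
#' Writes a `x,y` header and one point per row with 17 significant
#' digits, enough for an exact double-precision round trip through
#' [read_points()].
#'
#' @param points A point set.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_points <- function(points, path) {
  p <- .xy(points)
  writeLines(c("x,y", sprintf("%.17g,%.17g", p$x, p$y)), path)
  invisible(path)
}

#' Write a reduction result
#'
#' Writes the kept point indices (1-based input row numbers), one per
#' line, and optionally a JSON sidecar with the run statistics `n`, `s`,
#' `m_used` and `reduction_factor`.
#'
#' @param result A `reduction_result` from [reduce_points()].
#' @param path Output path for the index list.
#' @param stats_path Optional path for the JSON statistics.
#' @return Invisibly, `path`.
#' @export
write_reduction <- function(result, path, stats_path = NULL) {
  stopifnot(inherits(result, "reduction_result"))
  writeLines(as.character(result$indices), path)
  if (!is.null(stats_path)) {
    jsonlite::write_json(
      list(n = result$n, s = result$s, m_used = result$m_used,
           reduction_factor = result$reduction_factor),
      stats_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a hull polygon
#'
#' CSV output lists the vertices (index, x, y) in canonical
#' counterclockwise order. GeoJSON output writes a `Polygon` whose ring
#' is closed (the first vertex repeated last) per the GeoJSON standard.
#'
#' @param hull A `hull_polygon`.
#' @param path Output path.
#' @param format `"csv"` or `"geojson"`.
#' @return Invisibly, `path`.
#' @export
write_hull <- function(hull, path, format = c("csv", "geojson")) {
  stopifnot(inherits(hull, "hull_polygon"))
  format <- match.arg(format)
  if (format == "csv") {
    writeLines(c("index,x,y",
                 sprintf("%d,%.17g,%.17g", hull$indices, hull$x, hull$y)),
               path)
  } else {
    ring <- cbind(c(hull$x, hull$x[1L]), c(hull$y, hull$y[1L]))
    gj <- list(type = "Polygon",
               coordinates = list(lapply(seq_len(nrow(ring)),
                                         function(i) ring[i, ])))
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
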