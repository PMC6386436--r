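#' Coerce an object to a point set
#'
#' A point set is an n x 2 numeric matrix with columns `x` and `y`, one row
#' per point. Row order is meaningful: every index reported by the package
#' (hull vertices, reduced subsets) refers to the row number of the input.
#'
#' @param points A two-column numeric matrix or data frame. Columns named
#'   `x` and `y` are used if present, otherwise the first two columns.
#' @param check_finite Reject non-finite coordinates (`NA`, `NaN`, `Inf`)?
#'   The reduction and hull code assumes finite input.
#' @return An n x 2 numeric matrix with columns `x`, `y`.
#' @examples
#' as_points(data.frame(x = c(0, 1), y = c(2, 3)))
#' @export
as_points <- function(points, check_finite = TRUE) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) < 2L)
    stop("`points` must be a matrix or data frame with at least 2 columns")
  cn <- colnames(points)
  if (!is.null(cn) && all(c("x", "y") %in% cn)) {
    points <- points[, c("x", "y"), drop = FALSE]
  } else {
    points <- points[, 1:2, drop = FALSE]
  }
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  if (nrow(points) == 0L) stop("empty point set")
  if (check_finite) {
    bad <- which(!is.finite(points[, 1L]) | !is.finite(points[, 2L]))
    if (length(bad))
      stop("non-finite coordinates at row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "))
  }
  points
}

# internal: split a validated point matrix into coordinate vectors
.xy <- function(points) {
  points <- as_points(points)
  list(x = points[, 1L], y = points[, 2L], n = nrow(points))
}
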